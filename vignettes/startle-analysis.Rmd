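---
title: "Methods: startle EMG scoring and threat-task analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: startle EMG scoring and threat-task analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npustartle)
```

This vignette documents the models, parameter choices, and numerical
conventions behind `npustartle`. The package implements the analysis
chain of NPU threat-of-shock startle studies: schedule construction,
synthetic raw-EMG generation with ground truth, blink scoring,
difference-score aggregation, and the within-subject ANOVA.

## Experimental schedules

The NPU task alternates Neutral, Predictable and Unpredictable blocks in
one of two counterbalanced 8-block orders (`NPNUNUNP`, `NUNPNPNU`), one
per run; any two threat blocks are separated by a Neutral block, and the
builder rejects orders violating this. Per block, N contributes 2 probe
trials per phase (cue / ITI) and P and U contribute 4, giving 16 trials
per condition label over the two runs. Three shocks per run are placed
uniformly without replacement over the eligible intervals (P-cue, or any
U interval), at most one per trial.

Where the design's printed description leaves timing open, we fixed it
once as follows:

- **Cue duration** is 8 s (stated). **ITI durations** are unspecified and
  default to uniform 12–18 s, a typical pacing that keeps a run near
  9–10 minutes.
- **Probe latencies** inside intervals are unspecified. Probes are
  jittered uniformly — 3–5.5 s into the cue, and no earlier than 6 s
  into / no later than 5 s before the end of an ITI. These margins
  guarantee a minimum of 8 s between successive probes, the usual floor
  for avoiding startle-on-startle refractory attenuation. The bound is a
  structural consequence of the margins, not a rejection-sampling loop,
  so schedule generation is O(trials) and deterministic per seed.

The habituation series is 9 unsignaled probes ~17 s apart (uniform
±1.5 s jitter). The Sternberg builders reproduce the three session
variants (12 trials/condition targeting; 3 trials/condition/block ×
2 blocks × 2 runs testing+threat, plus 2 discarded shock trials per run;
4 trials/condition TMS) with exact instruction (1 s) and response-probe
(3 s) durations and jittered letters (1.5–2.5 s), retention
(6.5–8.5 s) and ITI (5–8 s) intervals; match/mismatch assignment is
balanced exactly within each trial-type × block-condition cell.

The iTBS builder is fully parametrized (trains, bursts per train, pulses
per burst, 50 Hz intra-burst and 5 Hz burst rates, 8 s inter-train gap)
because printed descriptions of "60-pulse trains ... for 2 s" are
arithmetically inconsistent with 3-pulse bursts at 5 Hz (2 s of triplets
is 30 pulses). The only unambiguous anchor is the 600-pulse session
dose, which the default configuration (10 trains × 20 bursts × 3 pulses)
realizes; the train-on time then comes out at 4 s. The builder rejects
parameter sets whose burst duration reaches the burst period. The shock
train is 2-ms pulses at 200 Hz filling 100 ms from t = 0 (20 pulses).

## Synthetic EMG model

A blink is modeled as band-limited Gaussian noise (default carrier band
70–250 Hz at 2000 Hz sampling) under a Hann amplitude window centered
`onset_latency_ms` (default 45 ms) after probe onset with compact
support of `burst_width_ms` (default 60 ms). Surface EMG is stochastic
interference, which is exactly the signal class for which
rectify-then-smooth is the appropriate envelope estimator. Two choices
deserve comment:

- **Compact support, not a Gaussian taper.** A Gaussian window wide
  enough to look blink-like leaves several percent of its amplitude at
  probe onset, which leaks blink energy backwards (through the
  zero-phase filter and the smoothing window) into the 50-ms pre-probe
  baseline, biasing baseline statistics by several µV. Real blink EMG
  begins after the probe; the Hann support `latency ± width/2`
  (15–75 ms post-probe by default) enforces that.
- **Per-burst calibration.** Each realized burst is rescaled so that the
  rectified-smoothed envelope of the isolated burst attains exactly the
  target amplitude over the scoring peak window. The envelope maximum of
  an uncalibrated stochastic burst has ~10–15% trial-to-trial spread,
  which would put a hard ceiling on any ground-truth recovery check;
  calibrating each realization makes "injected amplitude" a sharp,
  testable quantity. Scoring then recovers it up to baseline-noise
  interaction (a few percent at the default 2 µV noise floor against a
  150 µV base blink).

Per-trial ground-truth amplitude is
`base × condition multiplier × habituation_decay^(trial rank)`. Defaults:
base 150 µV; decay 0.98 per trial (a mild, realistic within-session
habituation); multipliers N = 1.0, P_iti = 1.15, U_cue = 1.5,
P_cue = 1.6, U_iti = 1.4 — threat potentiation with fear (cued)
potentiation exceeding anxiety (contextual) potentiation, the ordering
typical of healthy samples. No-blink trials (probability
`no_blink_prob`) carry amplitude 0; artifact trials have their pre-probe
noise (250 ms) multiplied by `artifact_gain` (default 8).

What the generator does *not* emulate: motor-unit biophysics,
shock-evoked EMG contamination, electrodermal activity, non-stationary
drift, or spontaneous blinks. Passing recovery tests on this generator
therefore shows the scoring chain is correct and well-calibrated for
probe-locked bursts in stationary noise — not that it is robust to every
artifact class in field recordings.

## Scoring chain and its numerical conventions

The chain is: 4th-order Butterworth 30–300 Hz bandpass applied forward
and backward (`signal::filtfilt`; zero phase preserves blink peak
latency), full-wave rectification, and a centered moving average over
`round(fs × 20 ms)` samples with reflection padding. Scoring windows are
converted to sample indices by rounding half up, with sample *j* at time
*j/fs*: baseline is the half-open window `[onset − 50 ms, onset)`, peak
the closed window `[onset + 20 ms, onset + 120 ms]`; raw amplitude =
peak max − baseline mean.

**Noisy-trial exclusion.** Trials whose baseline SD exceeds 2 × the run
SD are counted missing. "Run SD" is underdetermined in the usual verbal
statement of this rule; we define it as the *pooled within-window* SD
over the run's baseline windows, each window centered at its own mean.
The naive alternative (SD over the raw concatenation) is inflated by
between-trial baseline-mean shifts — precisely the signature of the
artifacts the rule is meant to catch — and under it a tenfold-amplified
baseline among 16 quiet trials is *not* flagged; the pooled form flags
it robustly. The whole-envelope alternative remains available
(`run_sd_scope = "whole_run"`).

**No-blink coding.** A trial whose peak fails to exceed
`baseline mean + (baseline max − min)` is coded 0 and *retained* in
normalization and condition means ("coded as 0" means kept as data, not
discarded). The comparison uses `<=` with an absolute floor of
10⁻⁹ × the largest peak in the table, so envelopes that are zero up to
numerical dust (denormal filter tails) count as flat. A literal
`peak < range` reading is available via `no_blink_rule = "range_only"`.
Under stationary baseline noise this published rule is intrinsically
statistical: both sides are extreme-value statistics of the same
process, and it codes roughly 75–85% of truly blink-free trials
regardless of noise level (the geometry is scale-invariant). It is
deterministic in the two regimes that matter for validation — flat
envelopes are always coded, and genuine blinks (tens of SDs above the
noise) never are.

**t-normalization.** Within each subject-session (per-run selectable),
non-missing raw amplitudes are z-scored with the sample (n−1) SD and
mapped to `t = z·10 + 50`; zero-coded trials are included, missing
trials get `NA`. Groups with fewer than 2 usable trials or zero variance
are an error naming the group.

## Outcomes

Condition means average non-missing trials per subject-session; a
subject-session lacking valid trials in any required condition is
dropped with a warning. `FPS = P_cue − P_iti` and
`APS_ITI = U_iti − N_iti` are exact subtractions, applied identically to
startle t-scores and 0–10 anxiety ratings.

Outlier truncation clamps values beyond mean ± 2·SD (sample SD) to the
bound, computing both moments from the *original* vector in a single
pass — re-estimating bounds after clamping would move values again, so
the pipeline applies truncation exactly once per analyzed vector. The
grouping is one vector per measure × session × score type across
subjects (the vectors the ANOVA consumes), and truncation is applied to
the difference scores rather than the condition means, since the
difference scores are the analyzed values; a useful algebraic fact,
asserted in the tests, is that vectors of ≤ 5 values are never truncated
at k = 2 (the maximum standardized deviation with a sample SD is
(n−1)/√n < 2).

Sternberg behavior aggregation discards shock trials before any
averaging (they exist only to deliver the shock), computes percent
correct and mean RT per cell, and forms sort − maintain difference
scores.

## Statistics

`rm_anova_2x2` implements the classical within-subject decomposition:
each term's error is its factor-by-subject interaction, F has (1, n−1)
df, and partial η² = SS_eff/(SS_eff + SS_err) = F·df1/(F·df1 + df2).
For two-level factors each F provably equals the squared paired-t on the
per-subject contrast; the tests verify this identity (tolerance 1e−8)
against `t.test` and the full table against `aov()` — the package never
delegates the decomposition to either, so the comparison is a genuine
dual route. Sphericity corrections are moot with two levels and are not
implemented. Subjects with missing cells are removed listwise with a
message. The partial-η² convention reproduces all eight published
(F, η²) pairs at df2 = 27 to two decimals, which is how the convention
was pinned down. Post-hoc paired t-tests report uncorrected p-values
(with the planning convention of a corrected two-tailed α = 0.025 noted
in the documentation), plus Cohen's d = mean(diff)/SD(diff).

Power for the paired contrast uses the exact noncentral-t formulation:
ncp = d√n against the central-t critical value; `required_n` returns the
smallest n reaching target power and is cross-checked against
`power.t.test(type = "paired")` and a vectorized Monte-Carlo oracle. At
d = 0.6, α = 0.025 (two-tailed), power 0.8 it returns n = 29, matching
the planning range of 25–30 subjects.

## Study-level simulation: two paths

`simulate_study_outcomes` draws difference scores directly on the
analysis scale: cell value = score-type mean + subject effect
(SD `between_subject_sd`, default 8 t-units) + coil shift + iid residual
(SD `within_cell_sd`, default 5 t-units). Standardized effects are
defined on the per-subject contrasts the ANOVA tests (so
`coil_effect_d` is exactly the paired-d of the active−sham contrast),
making noncentral-t power predictions exact; this generator drives the
500-replicate type-I and power calibrations, which confirm a ~5%
null rejection rate and agreement with the predicted power at the
implied d = √(F/n) = √(5.1/28) ≈ 0.43. Ratings carry a response-type
effect but no coil effect, mirroring a double-blind design in which
stimulation alters startle without changing subjective report; the
ratings response-type default is negative (APS > FPS) while startle's is
positive (FPS > APS), the dissociation typically observed.

`simulate_study` generates the full raw-EMG path (fresh NPU schedule,
recording and ratings per subject × session, seeds derived
deterministically from the master seed via a string-hash substream).
Because t-scoring renormalizes each session, a session-wide amplitude
gain cancels out of the difference scores; the coil effect must
therefore act on *relative* potentiation, implemented as a fractional
boost (`coil_potentiation_boost`, default 0.15) of each multiplier's
excess over 1 in active sessions. This path exists to exercise the whole
pipeline end to end with known per-trial truth; the outcome-level path
is the one with exact standardized-effect semantics, and replicate-level
calibration uses it because simulating thousands of full-EMG studies is
neither necessary for the tested contrast nor proportionate in cost.

## Problem sizes and determinism

All fixtures are generated in code. The test suite uses full-size single
sessions (96-probe NPU recordings, ~19-minute equivalents at 2000 Hz)
for scoring checks, 3–4 subjects for end-to-end pipeline checks, 100
randomized datasets (n = 4–28) for the F = t² identity, 1000 seeds for
the shock-placement uniformity test, and 500 replicate studies (n = 28)
for the calibration checks; the acceptance script mirrors these sizes.
Every stochastic routine takes an explicit seed and restores the
caller's RNG state, so identical seeds give bit-identical schedules,
recordings and result bundles.

## Known limitations

- The absolute µV scale of the generator is conventional; such studies
  publish no descriptive raw-amplitude statistics, so only relative
  structure (potentiation ratios, habituation, SNR) is meaningful.
- The noisy-trial flag and no-blink coding are rule-faithful
  reimplementations of tersely-stated conventions; both have documented
  configurable alternatives where the wording is ambiguous.
- The raw-EMG coil-effect mapping (potentiation boost) is monotone but
  not calibrated to a target standardized d; use the outcome-level
  generator when exact effect sizes matter.
- Ratings are simulated as truncated-normal trial values on 0–10;
  ordinal response styles (endpoint clumping) are not modeled.
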