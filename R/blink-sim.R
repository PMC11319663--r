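#' Blink simulation parameters
#'
#' Controls the synthetic orbicularis-oculi EMG generator. A blink is a
#' Gaussian-windowed band-limited noise burst — surface EMG is stochastic
#' interference, which makes rectify-then-smooth the right envelope
#' estimator — with onset latency and width typical of the acoustic
#' startle blink. Trial-to-trial structure: amplitude = `base_amplitude_uv`
#' x condition multiplier x `habituation_decay^(trial rank)`, with
#' optional no-blink trials (amplitude 0) and baseline artifacts (pre-probe
#' noise amplified by `artifact_gain`, which the noisy-trial flag should
#' catch).
#'
#' Default condition multipliers encode plausible threat potentiation:
#' fear-potentiated startle (P_cue vs P_iti) and anxiety-potentiated
#' startle (U_iti vs N_iti) both positive, fear larger than anxiety.
#'
#' @param base_amplitude_uv blink envelope amplitude for a multiplier-1,
#'   first-rank trial (microvolts).
#' @param onset_latency_ms blink envelope peak latency after probe onset.
#' @param burst_width_ms full width (FWHM) of the Gaussian amplitude
#'   window.
#' @param carrier_band_hz two-element band of the burst carrier noise.
#' @param baseline_noise_sd_uv SD of the continuous background noise.
#' @param habituation_decay per-trial multiplicative decay in (0, 1].
#' @param condition_multipliers named positive factors applied per
#'   condition label; labels absent from the map get 1.
#' @param artifact_prob,artifact_gain probability that a trial's pre-probe
#'   baseline noise is amplified, and the gain applied.
#' @param no_blink_prob probability that a trial carries no blink.
#' @param rng_seed integer seed; `NULL` uses the current RNG.
#' @return list of class `blink_sim_params`.
#' @export
blink_sim_params <- function(base_amplitude_uv = 150,
                             onset_latency_ms = 45,
                             burst_width_ms = 60,
                             carrier_band_hz = c(70, 250),
                             baseline_noise_sd_uv = 2,
                             habituation_decay = 0.98,
                             condition_multipliers = c(
                               N_cue = 1.0, N_iti = 1.0,
                               P_cue = 1.6, P_iti = 1.15,
                               U_cue = 1.5, U_iti = 1.4, HAB = 1.0),
                             artifact_prob = 0, artifact_gain = 8,
                             no_blink_prob = 0, rng_seed = NULL) {
  stopifnot(base_amplitude_uv >= 0, burst_width_ms > 0,
            baseline_noise_sd_uv >= 0)
  if (habituation_decay <= 0 || habituation_decay > 1) {
    stop_npu("`habituation_decay` must lie in (0, 1]")
  }
  if (any(condition_multipliers <= 0)) {
    stop_npu("condition multipliers must be strictly positive")
  }
  for (pr in c(artifact_prob, no_blink_prob)) {
    if (pr < 0 || pr > 1) stop_npu("probabilities must lie in [0, 1]")
  }
  if (artifact_gain <= 1) stop_npu("`artifact_gain` must exceed 1")
  structure(list(base_amplitude_uv = base_amplitude_uv,
                 onset_latency_ms = onset_latency_ms,
                 burst_width_ms = burst_width_ms,
                 carrier_band_hz = carrier_band_hz,
                 baseline_noise_sd_uv = baseline_noise_sd_uv,
                 habituation_decay = habituation_decay,
                 condition_multipliers = condition_multipliers,
                 artifact_prob = artifact_prob,
                 artifact_gain = artifact_gain,
                 no_blink_prob = no_blink_prob,
                 rng_seed = rng_seed),
            class = "blink_sim_params")
}

#' Generate one synthetic blink burst
#'
#' Band-limited Gaussian noise shaped by a Hann amplitude window centered
#' `latency_ms` after segment start with compact support
#' `latency_ms ± width_ms / 2` — compact support keeps blink energy out
#' of the pre-probe baseline window, as in a real blink whose EMG onset
#' follows the probe. Each realized burst is calibrated so that its
#' rectified-smoothed envelope — computed with the default scoring chain —
#' attains exactly `amplitude_uv` over the scoring peak window when the
#' burst is isolated; downstream scoring then recovers the injected
#' amplitude up to baseline-noise interaction.
#'
#' @param amplitude_uv target envelope peak; 0 returns a zero segment.
#' @param latency_ms envelope peak latency from segment start.
#' @param width_ms total support of the amplitude window.
#' @param carrier_band_hz carrier noise band (inside (0, fs/2)).
#' @param fs_hz sampling rate.
#' @return numeric vector covering `latency_ms + 2.5 * width_ms` ms,
#'   to be added to a recording at the probe onset sample.
#' @export
blink_burst <- function(amplitude_uv, latency_ms = 45, width_ms = 60,
                        carrier_band_hz = c(70, 250), fs_hz = 2000) {
  if (amplitude_uv < 0) stop_npu("`amplitude_uv` must be nonnegative")
  if (width_ms <= 0) stop_npu("`width_ms` must be positive")
  if (carrier_band_hz[1] <= 0 || carrier_band_hz[2] >= fs_hz / 2 ||
      carrier_band_hz[1] >= carrier_band_hz[2]) {
    stop_npu("carrier band must satisfy 0 < low < high < fs/2")
  }
  n <- round_half_up((latency_ms + width_ms) / 1000 * fs_hz) +
    round_half_up(0.025 * fs_hz)
  if (amplitude_uv == 0) return(numeric(n))

  bf <- signal::butter(4, carrier_band_hz / (fs_hz / 2), type = "pass")
  carrier <- signal::filtfilt(bf, stats::rnorm(n))
  t_ms <- (seq_len(n) - 1) / fs_hz * 1000
  half <- width_ms / 2
  w <- ifelse(abs(t_ms - latency_ms) < half,
              0.5 * (1 + cos(pi * (t_ms - latency_ms) / half)), 0)
  burst <- carrier * w

  # calibrate: isolated-burst envelope max over the scoring peak window
  # equals the target amplitude
  cfg <- scoring_config(fs_hz = fs_hz)
  pad <- round_half_up(0.1 * fs_hz)
  env <- preprocess_emg(c(numeric(pad), burst, numeric(pad)), cfg)
  w1 <- round_half_up(fs_hz * cfg$peak_window_ms[1] / 1000)
  w2 <- round_half_up(fs_hz * cfg$peak_window_ms[2] / 1000)
  peak <- max(env[(pad + w1 + 1):(pad + w2 + 1)])
  if (peak <= 0) stop_npu("degenerate burst realization")
  burst * (amplitude_uv / peak)
}

#' Simulate a continuous EMG session from a schedule
#'
#' Builds one `emg_recording` for an NPU or habituation schedule:
#' Gaussian background noise plus one calibrated blink burst per probe,
#' with condition-dependent potentiation, geometric habituation over trial
#' rank, and (optionally) no-blink trials and baseline artifacts. Multi-run
#' schedules are laid end to end on a single recording clock with
#' `run_gap_s` between runs; the per-trial ground truth (true amplitude,
#' artifact / no-blink flags) is stored alongside.
#'
#' @param schedule an `npu_schedule` or `habituation_schedule`.
#' @param params a [blink_sim_params()].
#' @param subject_id,session_label identifiers stamped on the recording;
#'   `session_label` is one of `"active"`, `"sham"`, `"pretest"`.
#' @param start_pad_s,end_pad_s,run_gap_s recording padding (seconds)
#'   before the first event, after the last, and between runs.
#' @param fs_hz sampling rate of the simulated recording.
#' @return An object of class `emg_recording`: `fs_hz`, `samples`,
#'   `events` (probe and shock rows on the recording clock), `subject_id`,
#'   `session_label`, `ground_truth`.
#' @export
simulate_session <- function(schedule, params = blink_sim_params(),
                             subject_id = "sub01",
                             session_label = "pretest",
                             start_pad_s = 2, end_pad_s = 1,
                             run_gap_s = 5, fs_hz = 2000) {
  stopifnot(inherits(params, "blink_sim_params"))
  fs <- fs_hz
  ev <- schedule_events(schedule, subject_id, session_label)

  # lay runs end to end on one recording clock
  run_ids <- sort(unique(ev$run))
  offset <- start_pad_s
  for (r in run_ids) {
    sel <- ev$run == r
    run_len <- max(ev$onset_s[sel]) + end_pad_s
    ev$onset_s[sel] <- ev$onset_s[sel] + offset
    offset <- offset + run_len + run_gap_s
  }
  total_s <- offset - run_gap_s + end_pad_s
  n <- ceiling(total_s * fs)

  probes <- ev[ev$event_type == "probe", ]
  probes <- probes[order(probes$onset_s), ]
  n_tr <- nrow(probes)

  with_seed(params$rng_seed, {
    samples <- stats::rnorm(n, 0, params$baseline_noise_sd_uv)
    mult <- params$condition_multipliers
    cond_mult <- ifelse(probes$condition_label %in% names(mult),
                        mult[probes$condition_label], 1)
    true_amp <- params$base_amplitude_uv * cond_mult *
      params$habituation_decay^(seq_len(n_tr) - 1)
    is_no_blink <- stats::runif(n_tr) < params$no_blink_prob
    is_artifact <- stats::runif(n_tr) < params$artifact_prob
    true_amp[is_no_blink] <- 0

    for (i in seq_len(n_tr)) {
      i0 <- onset_sample(probes$onset_s[i], fs)
      if (is_artifact[i]) {
        a <- max(1L, i0 - round_half_up(0.25 * fs))
        samples[a:i0] <- samples[a:i0] * params$artifact_gain
      }
      if (true_amp[i] > 0) {
        burst <- blink_burst(true_amp[i], params$onset_latency_ms,
                             params$burst_width_ms,
                             params$carrier_band_hz, fs)
        idx <- (i0 + 1):min(i0 + length(burst), n)
        samples[idx] <- samples[idx] + burst[seq_along(idx)]
      }
    }

    ground_truth <- data.frame(
      subject_id = subject_id, session = session_label,
      run = probes$run, trial_index = probes$trial_index,
      condition_label = probes$condition_label,
      probe_onset_s = probes$onset_s,
      true_amplitude_uv = true_amp,
      is_artifact = is_artifact, is_no_blink = is_no_blink,
      stringsAsFactors = FALSE
    )

    structure(list(fs_hz = fs, samples = samples, events = ev,
                   subject_id = subject_id, session_label = session_label,
                   ground_truth = ground_truth),
              class = "emg_recording")
  })
}
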