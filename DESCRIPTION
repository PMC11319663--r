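Package: npustartle
Title: Startle EMG Scoring and Threat-Task Outcome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for acoustic-startle experiments using the
    NPU (neutral / predictable / unpredictable) threat-of-shock paradigm and
    theta-burst stimulation sessions. Builds and validates timed experiment
    schedules (NPU runs, startle habituation, Sternberg working-memory
    variants, TBS and shock pulse trains), simulates orbicularis-oculi
    surface EMG with known ground truth, scores startle blinks from
    continuous EMG (bandpass, rectify, smooth, windowed peak minus
    baseline, noisy-trial exclusion, no-blink coding, t-score
    normalization), aggregates condition means into fear- and
    anxiety-potentiated startle difference scores, and runs the
    within-subject 2x2 repeated-measures ANOVA with partial eta-squared,
    post-hoc paired t-tests, and noncentral-t power computations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
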