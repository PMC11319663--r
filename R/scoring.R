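#' Startle scoring configuration
#'
#' Parameters of the EMG processing chain. Defaults follow standard
#' orbicularis-oculi startle practice: 30–300 Hz bandpass, rectification,
#' 20-ms moving-average smoothing, peak search 20–120 ms after probe
#' onset, 50-ms pre-probe baseline, and exclusion of trials whose baseline
#' SD exceeds twice the run SD.
#'
#' @param fs_hz sampling rate the recording is expected to have.
#' @param band_low_hz,band_high_hz bandpass corner frequencies.
#' @param smooth_window_ms width of the centered moving-average window.
#' @param peak_window_ms post-probe window (start, end), inclusive end.
#' @param baseline_window_ms pre-probe baseline length; window is
#'   half-open `[onset - baseline, onset)`.
#' @param noise_multiplier trials with baseline SD above
#'   `noise_multiplier` times the run SD are counted missing.
#' @param run_sd_scope `"baseline"` (pooled within-window SD over the
#'   run's baseline windows, each centered at its own mean; robust to
#'   blink energy and baseline shifts) or `"whole_run"` (SD of the full
#'   envelope).
#' @param no_blink_rule `"mean_plus_range"` codes a trial 0 when
#'   peak < baseline mean + (baseline max − min); `"range_only"` is the
#'   literal peak < (max − min) reading.
#' @return list of class `scoring_config`.
#' @export
scoring_config <- function(fs_hz = 2000, band_low_hz = 30,
                           band_high_hz = 300, smooth_window_ms = 20,
                           peak_window_ms = c(20, 120),
                           baseline_window_ms = 50, noise_multiplier = 2,
                           run_sd_scope = c("baseline", "whole_run"),
                           no_blink_rule = c("mean_plus_range",
                                             "range_only")) {
  run_sd_scope <- match.arg(run_sd_scope)
  no_blink_rule <- match.arg(no_blink_rule)
  if (band_low_hz <= 0 || band_low_hz >= band_high_hz) {
    stop_npu("need 0 < band_low_hz < band_high_hz")
  }
  if (band_high_hz >= fs_hz / 2) {
    stop_npu("band_high_hz (", band_high_hz, ") must be below the Nyquist ",
             "frequency ", fs_hz / 2, " Hz")
  }
  if (smooth_window_ms <= 0 || baseline_window_ms <= 0) {
    stop_npu("window lengths must be positive")
  }
  if (peak_window_ms[1] >= peak_window_ms[2]) {
    stop_npu("peak window start must precede its end")
  }
  structure(list(fs_hz = fs_hz, band_low_hz = band_low_hz,
                 band_high_hz = band_high_hz,
                 smooth_window_ms = smooth_window_ms,
                 peak_window_ms = peak_window_ms,
                 baseline_window_ms = baseline_window_ms,
                 noise_multiplier = noise_multiplier,
                 run_sd_scope = run_sd_scope,
                 no_blink_rule = no_blink_rule),
            class = "scoring_config")
}

#' Bandpass, rectify and smooth an EMG trace
#'
#' Zero-phase 4th-order Butterworth bandpass (applied forward and
#' backward, preserving blink peak latency), full-wave rectification, and
#' a centered moving average over `round(fs * smooth_window)` samples with
#' reflection padding at the edges. Output length equals input length.
#'
#' @param x numeric vector of raw EMG samples (microvolts), or an
#'   `emg_recording` (its `samples` are used).
#' @param cfg a [scoring_config()]; its `fs_hz` must match the recording.
#' @return nonnegative numeric envelope, same length as the input.
#' @export
preprocess_emg <- function(x, cfg = scoring_config()) {
  if (inherits(x, "emg_recording")) {
    if (x$fs_hz != cfg$fs_hz) {
      stop_npu("recording sampled at ", x$fs_hz,
               " Hz but config expects ", cfg$fs_hz, " Hz")
    }
    x <- x$samples
  }
  fs <- cfg$fs_hz
  if (cfg$band_high_hz >= fs / 2) {
    stop_npu("sampling rate too low for the configured band")
  }
  bf <- signal::butter(4, c(cfg$band_low_hz, cfg$band_high_hz) / (fs / 2),
                       type = "pass")
  filtered <- signal::filtfilt(bf, x)
  rectified <- abs(filtered)
  k <- round_half_up(fs * cfg$smooth_window_ms / 1000)
  moving_average(rectified, k)
}

# Centered moving average of window k with reflection padding.
# For even k the window spans floor((k-1)/2) samples left and
# ceiling((k-1)/2) right of the center.
moving_average <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  left <- (k - 1L) %/% 2L
  right <- k - 1L - left
  padded <- c(rev(x[seq_len(left)]), x, rev(x[n - seq_len(right) + 1L]))
  cs <- cumsum(c(0, padded))
  (cs[(k + 1):(n + k)] - cs[seq_len(n)]) / k
}

# 0-based sample index of a time point (sample j sits at time j/fs).
onset_sample <- function(onset_s, fs) round_half_up(onset_s * fs)

# Window index arithmetic shared by score_trial and the noisy-trial flag.
# Returns 1-based R index ranges.
trial_windows <- function(onset_s, cfg) {
  fs <- cfg$fs_hz
  i0 <- onset_sample(onset_s, fs)
  nb <- round_half_up(fs * cfg$baseline_window_ms / 1000)
  p1 <- i0 + round_half_up(fs * cfg$peak_window_ms[1] / 1000)
  p2 <- i0 + round_half_up(fs * cfg$peak_window_ms[2] / 1000)
  list(baseline = (i0 - nb + 1L):i0,      # [onset - b, onset), 0-based
       peak = (p1 + 1L):(p2 + 1L))       # [onset + s, onset + e], inclusive
}

#' Score one startle trial from an envelope
#'
#' Raw startle amplitude is the envelope peak (maximum over the 20–120 ms
#' post-probe window, inclusive end) minus the baseline (mean over the
#' 50 ms immediately preceding probe onset, half-open window). Window
#' endpoints are converted to samples by rounding half up.
#'
#' @param envelope output of [preprocess_emg()].
#' @param probe_onset_s probe onset in seconds from recording start.
#' @param cfg a [scoring_config()].
#' @return list with `raw_uv` (peak − baseline), `baseline_mean_uv`,
#'   `baseline_sd_uv`, `baseline_range_uv`, `peak_uv`.
#' @export
score_trial <- function(envelope, probe_onset_s, cfg = scoring_config()) {
  w <- trial_windows(probe_onset_s, cfg)
  if (w$baseline[1] < 1L || w$peak[length(w$peak)] > length(envelope)) {
    stop_npu("probe at ", probe_onset_s,
             " s: scoring windows fall outside the recording")
  }
  base <- envelope[w$baseline]
  peak_seg <- envelope[w$peak]
  baseline_mean <- mean(base)
  peak <- max(peak_seg)
  list(raw_uv = peak - baseline_mean,
       baseline_mean_uv = baseline_mean,
       baseline_sd_uv = stats::sd(base),
       baseline_range_uv = max(base) - min(base),
       peak_uv = peak)
}

#' Flag excessively noisy trials as missing
#'
#' The run SD is the pooled within-window standard deviation of the
#' envelope over all baseline windows in the run — each window is
#' centered at its own mean before pooling, so the reference is robust
#' both to blink energy and to between-trial baseline shifts (an
#' artifact-inflated window would otherwise raise the reference it is
#' compared against) — or, with `run_sd_scope = "whole_run"`, the SD of
#' the full envelope. Trials whose own baseline SD exceeds
#' `noise_multiplier x run SD` are set to `status = "missing_noisy"` and
#' are excluded from normalization and condition means downstream.
#'
#' @param trials trial-score data.frame from [score_recording()]'s internal
#'   scoring pass (needs `run`, `probe_onset_s`, `baseline_sd_uv`,
#'   `status`).
#' @param envelope the run-covering envelope the trials were scored on.
#' @param cfg a [scoring_config()].
#' @return `trials` with `status` and `run_sd_uv` updated.
#' @export
flag_noisy <- function(trials, envelope, cfg = scoring_config()) {
  if (nrow(trials) == 0L) stop_npu("no trials to flag")
  for (r in unique(trials$run)) {
    sel <- trials$run == r
    run_sd <- if (cfg$run_sd_scope == "whole_run") {
      stats::sd(envelope)
    } else {
      centered <- lapply(trials$probe_onset_s[sel], function(on) {
        w <- envelope[trial_windows(on, cfg)$baseline]
        w - mean(w)
      })
      stats::sd(unlist(centered))
    }
    noisy <- sel & trials$baseline_sd_uv > cfg$noise_multiplier * run_sd
    trials$status[noisy] <- "missing_noisy"
    trials$run_sd_uv[sel] <- run_sd
  }
  trials
}

#' Code no-blink trials as zero
#'
#' A trial whose envelope peak fails to exceed its baseline excursion is
#' treated as containing no blink: its raw amplitude is recorded as 0 and
#' it *remains* in normalization and condition means. Default rule: coded
#' when the peak does not exceed baseline mean + (baseline max − min);
#' `no_blink_rule = "range_only"` compares the peak against the bare
#' max − min instead.
#'
#' @inheritParams flag_noisy
#' @return `trials` with `status` and `raw_uv` updated.
#' @export
code_no_blink <- function(trials, cfg = scoring_config()) {
  thr <- switch(cfg$no_blink_rule,
    mean_plus_range = trials$baseline_mean_uv + trials$baseline_range_uv,
    range_only = trials$baseline_range_uv
  )
  # absolute floor at machine scale relative to the largest peak in the
  # table, so envelopes that are zero up to numerical dust count as flat
  eps <- 1e-9 * max(trials$peak_uv, 0)
  nb <- trials$status != "missing_noisy" & trials$peak_uv <= thr + eps
  trials$status[nb] <- "zero_no_blink"
  trials$raw_uv[nb] <- 0
  trials
}

#' Convert raw startle amplitudes to t-scores
#'
#' Within each normalization group (default: one subject-session), raw
#' amplitudes of non-missing trials (zero-coded no-blink trials included)
#' are z-scored with the sample (n−1) standard deviation and mapped to
#' t-scores, `t = z * 10 + 50`. Missing trials get `NA`.
#'
#' @param trials trial-score data.frame with `raw_uv` and `status`.
#' @param group_by `"session"` (one group per subject-session) or `"run"`.
#' @return `trials` with `z` and `t` columns filled.
#' @export
t_normalize <- function(trials, group_by = c("session", "run")) {
  group_by <- match.arg(group_by)
  key <- paste(trials$subject_id, trials$session,
               if (group_by == "run") trials$run else "")
  trials$z <- NA_real_
  trials$t <- NA_real_
  for (g in unique(key)) {
    sel <- key == g & trials$status != "missing_noisy"
    raws <- trials$raw_uv[sel]
    if (length(raws) < 2L) {
      stop_npu("normalization group '", trimws(g),
               "' has fewer than 2 usable trials")
    }
    s <- stats::sd(raws)
    if (s == 0) {
      stop_npu("normalization group '", trimws(g),
               "' has zero variance; t-scores undefined")
    }
    z <- (raws - mean(raws)) / s
    trials$z[sel] <- z
    trials$t[sel] <- z * 10 + 50
  }
  trials
}

#' Score every probe trial of a continuous EMG recording
#'
#' Runs the full chain: envelope extraction ([preprocess_emg()]), windowed
#' peak-minus-baseline scoring per probe event ([score_trial()]),
#' noisy-trial exclusion ([flag_noisy()]), no-blink zero-coding
#' ([code_no_blink()]), and t-score normalization ([t_normalize()]).
#'
#' @param recording an `emg_recording` (see [simulate_session()] or
#'   [read_signal()]); probe events are taken from `recording$events`.
#' @param cfg a [scoring_config()].
#' @param group_by normalization grouping, see [t_normalize()].
#' @return data.frame of class `trial_scores`: subject_id, session, run,
#'   trial_index, condition_label, probe_onset_s, raw_uv, baseline and
#'   peak measures, z, t, status.
#' @export
score_recording <- function(recording, cfg = scoring_config(),
                            group_by = "session") {
  stopifnot(inherits(recording, "emg_recording"))
  envelope <- preprocess_emg(recording, cfg)
  probes <- recording$events[recording$events$event_type == "probe", ]
  if (nrow(probes) == 0L) stop_npu("recording contains no probe events")
  scored <- lapply(probes$onset_s, function(on)
    score_trial(envelope, on, cfg))
  trials <- data.frame(
    subject_id = recording$subject_id,
    session = recording$session_label,
    run = probes$run,
    trial_index = probes$trial_index,
    condition_label = probes$condition_label,
    probe_onset_s = probes$onset_s,
    raw_uv = vapply(scored, `[[`, numeric(1), "raw_uv"),
    baseline_mean_uv = vapply(scored, `[[`, numeric(1), "baseline_mean_uv"),
    baseline_sd_uv = vapply(scored, `[[`, numeric(1), "baseline_sd_uv"),
    baseline_range_uv = vapply(scored, `[[`, numeric(1), "baseline_range_uv"),
    peak_uv = vapply(scored, `[[`, numeric(1), "peak_uv"),
    run_sd_uv = NA_real_,
    status = "valid",
    stringsAsFactors = FALSE
  )
  trials <- flag_noisy(trials, envelope, cfg)
  trials <- code_no_blink(trials, cfg)
  trials <- t_normalize(trials, group_by = group_by)
  class(trials) <- c("trial_scores", class(trials))
  trials
}
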