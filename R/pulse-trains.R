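#' Build an intermittent theta-burst stimulation (iTBS) pulse schedule
#'
#' iTBS delivers short trains of triplet bursts: `pulses_per_burst` pulses
#' at `intra_burst_rate_hz` (50 Hz) form one burst, bursts repeat at
#' `burst_rate_hz` (5 Hz, i.e. every 200 ms) within a train, and trains are
#' separated by `inter_train_gap_s`. The default session is ten trains of
#' 20 triplet bursts (60 pulses per train) for a 600-pulse dose.
#'
#' @param n_trains number of trains (default 10).
#' @param bursts_per_train bursts per train (default 20).
#' @param pulses_per_burst pulses per burst (default 3).
#' @param intra_burst_rate_hz within-burst pulse rate (default 50).
#' @param burst_rate_hz burst repetition rate within a train (default 5).
#' @param inter_train_gap_s gap between train offset and next train onset
#'   (default 8).
#' @return An object of class `pulse_train_schedule`: `pulse_times_s`
#'   (strictly increasing), `train` (train index per pulse), `params`.
#' @examples
#' length(build_itbs_schedule()$pulse_times_s)  # 600
#' @export
build_itbs_schedule <- function(n_trains = 10, bursts_per_train = 20,
                                pulses_per_burst = 3,
                                intra_burst_rate_hz = 50, burst_rate_hz = 5,
                                inter_train_gap_s = 8) {
  counts <- c(n_trains, bursts_per_train, pulses_per_burst)
  rates <- c(intra_burst_rate_hz, burst_rate_hz)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop_npu("train/burst/pulse counts must be positive integers")
  }
  if (any(rates <= 0) || inter_train_gap_s < 0) {
    stop_npu("rates must be positive and the inter-train gap nonnegative")
  }
  if (intra_burst_rate_hz <= burst_rate_hz) {
    stop_npu("`intra_burst_rate_hz` must exceed `burst_rate_hz`")
  }
  burst_dur <- (pulses_per_burst - 1) / intra_burst_rate_hz
  if (bursts_per_train > 1 && burst_dur >= 1 / burst_rate_hz) {
    stop_npu("burst duration (", burst_dur, " s) must be shorter than the ",
             "burst period (", 1 / burst_rate_hz, " s)")
  }
  train_on_s <- bursts_per_train / burst_rate_hz
  train_onsets <- (seq_len(n_trains) - 1) * (train_on_s + inter_train_gap_s)
  burst_offsets <- (seq_len(bursts_per_train) - 1) / burst_rate_hz
  pulse_offsets <- (seq_len(pulses_per_burst) - 1) / intra_burst_rate_hz
  per_train <- as.vector(outer(pulse_offsets, burst_offsets, `+`))
  times <- as.vector(outer(per_train, train_onsets, `+`))
  structure(
    list(pulse_times_s = times,
         train = rep(seq_len(n_trains), each = length(per_train)),
         params = list(n_trains = n_trains,
                       bursts_per_train = bursts_per_train,
                       pulses_per_burst = pulses_per_burst,
                       intra_burst_rate_hz = intra_burst_rate_hz,
                       burst_rate_hz = burst_rate_hz,
                       train_on_s = train_on_s,
                       inter_train_gap_s = inter_train_gap_s)),
    class = "pulse_train_schedule"
  )
}

#' Build an electric-shock pulse train
#'
#' A brief constant-rate train of rectangular pulses (default: 100 ms of
#' 2-ms pulses at 200 Hz, i.e. 20 pulses starting at t = 0).
#'
#' @param duration_ms train duration in milliseconds.
#' @param rate_hz pulse rate.
#' @param pulse_width_ms width of each pulse; must be below the pulse
#'   period.
#' @return A `pulse_train_schedule` with one train.
#' @export
build_shock_pulse_train <- function(duration_ms = 100, rate_hz = 200,
                                    pulse_width_ms = 2) {
  if (duration_ms <= 0 || rate_hz <= 0 || pulse_width_ms <= 0) {
    stop_npu("duration, rate and pulse width must be positive")
  }
  period_ms <- 1000 / rate_hz
  if (pulse_width_ms >= period_ms) {
    stop_npu("pulse width (", pulse_width_ms, " ms) must be below the ",
             "pulse period (", period_ms, " ms)")
  }
  n <- floor(duration_ms / period_ms + 1e-9)
  n <- max(n, 1L)
  times <- (seq_len(n) - 1) * period_ms / 1000
  structure(
    list(pulse_times_s = times, train = rep(1L, n),
         params = list(n_trains = 1L, duration_ms = duration_ms,
                       rate_hz = rate_hz, pulse_width_ms = pulse_width_ms)),
    class = "pulse_train_schedule"
  )
}

#' @export
schedule_events.pulse_train_schedule <- function(schedule,
                                                 subject_id = "sub01",
                                                 session = "tms") {
  n <- length(schedule$pulse_times_s)
  width_s <- if (!is.null(schedule$params$pulse_width_ms)) {
    schedule$params$pulse_width_ms / 1000
  } else 0
  event_row(subject_id, session, 1L, schedule$train, "T",
            seq_len(n), "pulse", "pulse", schedule$pulse_times_s, width_s,
            "pulse")
}
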