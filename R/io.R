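# CSV dialects shared by the pipeline: dot decimal separator, UTF-8,
# Unix newlines, times in seconds printed with 6 decimal places.

SIGNAL_HEADER <- c("time_s", "emg_uv")
EVENT_HEADER <- c("subject_id", "session", "run", "block_index",
                  "block_type", "trial_index", "phase", "event_type",
                  "onset_s", "duration_s", "condition_label")

#' Construct an EMG recording object
#'
#' Container tying a continuous single-channel EMG trace to its event
#' table. Validates that samples are finite, events sorted by onset within
#' run, and that every probe leaves room for the baseline window before it
#' and the scoring window after it.
#'
#' @param samples numeric microvolt trace.
#' @param fs_hz sampling rate (default 2000).
#' @param events event data.frame in the standard schedule-event format
#'   (see [schedule_events()]), onsets on the recording clock.
#' @param subject_id,session_label identifiers.
#' @param ground_truth optional per-trial simulation truth.
#' @return object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs_hz = 2000, events,
                          subject_id = "sub01",
                          session_label = "pretest",
                          ground_truth = NULL) {
  if (!all(is.finite(samples))) stop_npu("samples must be finite")
  validate_events(events)
  probes <- events[events$event_type == "probe", ]
  lo <- 0.050 * fs_hz
  hi <- 0.120 * fs_hz
  bad <- onset_sample(probes$onset_s, fs_hz) - lo < 0 |
    onset_sample(probes$onset_s, fs_hz) + hi + 1 > length(samples)
  if (any(bad)) {
    stop_npu("probe(s) at ",
             paste(round(probes$onset_s[bad], 3), collapse = ", "),
             " s leave no room for baseline/scoring windows")
  }
  structure(list(fs_hz = fs_hz, samples = samples, events = events,
                 subject_id = subject_id, session_label = session_label,
                 ground_truth = ground_truth),
            class = "emg_recording")
}

validate_events <- function(events) {
  miss <- setdiff(EVENT_HEADER, names(events))
  if (length(miss)) {
    stop_npu("event table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (any(!is.finite(events$onset_s))) {
    stop_npu("event onsets contain non-finite values at row(s) ",
             paste(which(!is.finite(events$onset_s)), collapse = ", "))
  }
  for (r in unique(events$run)) {
    on <- events$onset_s[events$run == r]
    if (is.unsorted(on)) {
      first <- which(events$run == r)[which(diff(on) < 0)[1] + 1L]
      stop_npu("event onsets not sorted within run ", r,
               "; first offending row: ", first)
    }
  }
  invisible(events)
}

#' Write / read a continuous signal CSV
#'
#' Two columns, `time_s` and `emg_uv`, both printed with 6 decimal
#' places. `read_signal` validates the header, monotone time, and absence
#' of non-finite values, and infers the sampling rate from the median
#' time step.
#'
#' @param recording an `emg_recording` (or list with `samples`, `fs_hz`).
#' @param path file path.
#' @return `read_signal`: list with `samples`, `fs_hz`, `time_s`.
#' @export
write_signal <- function(recording, path) {
  t <- (seq_along(recording$samples) - 1) / recording$fs_hz
  lines <- c(paste(SIGNAL_HEADER, collapse = ","),
             sprintf("%.6f,%.6f", t, recording$samples))
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), SIGNAL_HEADER)) {
    stop_npu(path, ": expected header '",
             paste(SIGNAL_HEADER, collapse = ","), "'")
  }
  bad <- which(!is.finite(df$time_s) | !is.finite(df$emg_uv))
  if (length(bad)) {
    stop_npu(path, ": non-finite value at line ", bad[1] + 1L)
  }
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    stop_npu(path, ": time column not strictly increasing (line ",
             which(diff(df$time_s) <= 0)[1] + 2L, ")")
  }
  fs <- 1 / stats::median(diff(df$time_s))
  list(samples = df$emg_uv, fs_hz = round(fs), time_s = df$time_s)
}

#' Write / read an event table CSV
#'
#' Standard columnar event format (see [schedule_events()]); times are
#' printed with 6 decimal places. Reading validates the header and sorted
#' onsets and reports the first offending line.
#'
#' @param events event data.frame.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  ev <- events
  ev$onset_s <- sprintf("%.6f", ev$onset_s)
  ev$duration_s <- sprintf("%.6f", ev$duration_s)
  utils::write.csv(ev[, EVENT_HEADER], path, row.names = FALSE,
                   quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), EVENT_HEADER)) {
    stop_npu(path, ": expected header '",
             paste(EVENT_HEADER, collapse = ","), "'")
  }
  validate_events(df)
  df
}

#' Write / read a generic pipeline table CSV
#'
#' Plain CSV with all numeric columns printed at 6 decimal places, so
#' that write-then-read round-trips values exactly at that precision.
#'
#' @param table data.frame.
#' @param path file path.
#' @export
write_table <- function(table, path) {
  out <- table
  for (cc in names(out)) {
    if (is.numeric(out[[cc]]) && !is.integer(out[[cc]])) {
      out[[cc]] <- sprintf("%.6f", out[[cc]])
      out[[cc]][out[[cc]] == "NA"] <- ""
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
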