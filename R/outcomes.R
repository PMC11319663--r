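NPU_CONDITIONS <- c("N_cue", "N_iti", "P_cue", "P_iti", "U_cue", "U_iti")

#' Per-condition means for startle t-scores or ratings
#'
#' Averages trial-level values within each NPU condition per
#' subject-session, using non-missing trials only (zero-coded no-blink
#' trials are data and are included). A subject-session lacking valid
#' trials in any required condition is dropped with a warning.
#'
#' @param trials trial-level data.frame: `subject_id`, `session`,
#'   `condition_label`, `status`, and the value column (`t` for startle
#'   scores from [score_recording()], `rating` for ratings tables).
#' @param measure `"startle_t"` or `"rating"`; picks the value column
#'   unless `value_col` is given.
#' @param value_col name of the value column; default from `measure`.
#' @param conditions required condition labels (default: the six NPU
#'   labels).
#' @return data.frame of class `outcome_table`: one row per
#'   subject-session with `measure`, one mean column per condition, and
#'   `n_valid_<condition>` counts.
#' @export
condition_means <- function(trials,
                            measure = c("startle_t", "rating"),
                            value_col = NULL,
                            conditions = NPU_CONDITIONS) {
  measure <- match.arg(measure)
  if (nrow(trials) == 0L) stop_npu("empty trial table")
  value_col <- value_col %||% switch(measure, startle_t = "t",
                                     rating = "rating")
  if (!value_col %in% names(trials)) {
    stop_npu("trial table has no '", value_col, "' column")
  }
  status <- if ("status" %in% names(trials)) trials$status else "valid"
  usable <- trials[status != "missing_noisy", , drop = FALSE]

  keys <- unique(usable[, c("subject_id", "session")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- usable[usable$subject_id == keys$subject_id[i] &
                    usable$session == keys$session[i], , drop = FALSE]
    m <- vapply(conditions, function(cc)
      mean(sub[[value_col]][sub$condition_label == cc]), numeric(1))
    nv <- vapply(conditions, function(cc)
      sum(sub$condition_label == cc), integer(1))
    if (any(nv == 0L)) {
      warning("dropping ", keys$subject_id[i], "/", keys$session[i],
              ": no valid trials in ",
              paste(conditions[nv == 0L], collapse = ", "), call. = FALSE)
      next
    }
    row <- data.frame(subject_id = keys$subject_id[i],
                      session = keys$session[i], measure = measure,
                      stringsAsFactors = FALSE)
    row[conditions] <- as.list(m)
    row[paste0("n_valid_", conditions)] <- as.list(nv)
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) stop_npu("no subject-session had complete conditions")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("outcome_table", class(out))
  out
}

#' Fear- and anxiety-potentiated startle difference scores
#'
#' Adds the two analyzed difference scores to an outcome table:
#' `FPS = P_cue − P_iti` (fear-potentiated startle: response to the
#' predictable-threat cue over that condition's intertrial interval) and
#' `APS_ITI = U_iti − N_iti` (anxiety-potentiated startle: unpredictable-
#' threat intertrial interval over the neutral one). Both measures
#' (startle t-scores, ratings) are treated identically.
#'
#' @param table an `outcome_table` from [condition_means()].
#' @return the table with `FPS` and `APS_ITI` columns.
#' @export
difference_scores <- function(table) {
  need <- c("P_cue", "P_iti", "U_iti", "N_iti")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop_npu("outcome table lacks condition mean(s): ",
             paste(miss, collapse = ", "))
  }
  table$FPS <- table$P_cue - table$P_iti
  table$APS_ITI <- table$U_iti - table$N_iti
  table
}

#' Truncate outliers to mean ± k·SD
#'
#' Single-pass winsorization at `k` sample standard deviations: with M
#' and SD the mean and (n−1) SD of the *original* vector, values above
#' `M + k·SD` are set to that bound and values below `M − k·SD` to the
#' lower bound. Bounds are never re-estimated after clamping. Applied per
#' analyzed vector (one measure, one score type, one session, across
#' subjects).
#'
#' @param values numeric vector (length >= 2; constant vectors pass
#'   through unchanged).
#' @param k bound multiplier (default 2).
#' @return the truncated vector.
#' @examples
#' truncate_outliers(c(0, 0, 0, 0, 0, 0, 0, 8))  # 8 -> 1 + 2*sqrt(8)
#' @export
truncate_outliers <- function(values, k = 2) {
  if (length(values) < 2L) stop_npu("need at least 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) return(values)
  pmin(pmax(values, m - k * s), m + k * s)
}

#' Aggregate Sternberg behavioral responses
#'
#' Discards shock trials (included in the design only to deliver shocks,
#' never analyzed), averages accuracy and reaction time per
#' subject-session by trial type and block condition, and forms the
#' working-memory difference scores (sort − maintain).
#'
#' @param responses data.frame with `subject_id`, `session`,
#'   `trial_type` (`sort` / `maintain`), `block_condition`,
#'   `is_shock_trial`, `correct` (logical), `rt_s` (positive seconds).
#' @return list with `cells` (percent_correct and mean_rt_s per
#'   subject-session-type-condition) and `wm_difference` (sort − maintain
#'   per subject-session-condition, for accuracy and RT).
#' @export
behavior_aggregate <- function(responses) {
  if (nrow(responses) == 0L) stop_npu("empty response table")
  keep <- responses[!responses$is_shock_trial, , drop = FALSE]
  if (any(keep$rt_s <= 0)) stop_npu("reaction times must be positive")
  agg <- stats::aggregate(
    cbind(percent_correct = 100 * keep$correct, mean_rt_s = keep$rt_s),
    by = keep[, c("subject_id", "session", "trial_type",
                  "block_condition")],
    FUN = mean
  )
  full <- expand.grid(trial_type = unique(keep$trial_type),
                      block_condition = unique(keep$block_condition),
                      stringsAsFactors = FALSE)
  for (key in split(agg, paste(agg$subject_id, agg$session))) {
    have <- paste(key$trial_type, key$block_condition)
    want <- paste(full$trial_type, full$block_condition)
    if (!all(want %in% have)) {
      stop_npu("subject ", key$subject_id[1], "/", key$session[1],
               " has an empty behavioral cell")
    }
  }
  sorts <- agg[agg$trial_type == "sort", ]
  maints <- agg[agg$trial_type == "maintain", ]
  merged <- merge(sorts, maints,
                  by = c("subject_id", "session", "block_condition"),
                  suffixes = c("_sort", "_maintain"))
  merged$wm_percent_correct <- merged$percent_correct_sort -
    merged$percent_correct_maintain
  merged$wm_rt_s <- merged$mean_rt_s_sort - merged$mean_rt_s_maintain
  list(cells = agg,
       wm_difference = merged[, c("subject_id", "session",
                                  "block_condition",
                                  "wm_percent_correct", "wm_rt_s")])
}
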