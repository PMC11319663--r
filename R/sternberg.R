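#' Build a Sternberg working-memory session schedule
#'
#' Three session variants share the same trial skeleton: a 1-s instruction
#' cue ("sort" or "maintain"), a jittered letter series (1.5–2.5 s), a
#' jittered retention interval (6.5–8.5 s), a fixed 3-s response probe, and
#' a jittered 5–8 s intertrial interval. Half of the trials in each
#' condition cell are matches.
#'
#' * `"targeting"` — one run, no threat blocks, default 12 trials per trial
#'   type (`block_condition = "none"`).
#' * `"testing_threat"` — two runs of alternating safe / threat blocks
#'   (two of each per run), default 3 trials per type per block, i.e. 12
#'   per trial-type-by-block-condition cell across the session. Two extra
#'   shock trials per run are inserted into random threat-block positions;
#'   they are flagged `is_shock_trial` and are meant to be discarded before
#'   any behavioral aggregation.
#' * `"tms"` — one short run, no threat, default 4 trials per type.
#'
#' @param session_kind one of `"targeting"`, `"testing_threat"`, `"tms"`.
#' @param trials_per_condition trials per trial type (per block for
#'   `testing_threat`); `NULL` uses the variant default above.
#' @param rng_seed integer seed; `NULL` uses the current RNG.
#' @return An object of class `sternberg_schedule`: list with `trials`
#'   (run, block_index, block_condition, trial_index, trial_type,
#'   instruction_s, letters_s, retention_s, probe_s, iti_s, is_match,
#'   is_shock_trial, onset_s) and `session_kind`.
#' @export
build_sternberg_schedule <- function(session_kind = c("targeting",
                                                      "testing_threat",
                                                      "tms"),
                                     trials_per_condition = NULL,
                                     rng_seed = NULL) {
  session_kind <- match.arg(session_kind)
  trials <- with_seed(rng_seed, {
    switch(session_kind,
      targeting = sternberg_plain_run(trials_per_condition %||% 12, run = 1L),
      tms = sternberg_plain_run(trials_per_condition %||% 4, run = 1L),
      testing_threat = sternberg_threat_session(trials_per_condition %||% 3)
    )
  })
  trials <- add_sternberg_onsets(trials)
  structure(list(session_kind = session_kind, trials = trials),
            class = "sternberg_schedule")
}

sternberg_durations <- function(n) {
  data.frame(
    instruction_s = rep(1, n),
    letters_s = stats::runif(n, 1.5, 2.5),
    retention_s = stats::runif(n, 6.5, 8.5),
    probe_s = rep(3, n),
    iti_s = stats::runif(n, 5, 8)
  )
}

balanced_matches <- function(n, label) {
  if (n %% 2L != 0L) {
    stop_npu(label, ": ", n,
             " trials cannot be split evenly into matches and mismatches")
  }
  sample(rep(c(TRUE, FALSE), n / 2L))
}

sternberg_plain_run <- function(n_per_type, run) {
  types <- sample(rep(c("sort", "maintain"), n_per_type))
  n <- length(types)
  match_by_type <- lapply(c(sort = "sort", maintain = "maintain"), function(tt)
    balanced_matches(sum(types == tt), tt))
  is_match <- logical(n)
  for (tt in c("sort", "maintain")) {
    is_match[types == tt] <- match_by_type[[tt]]
  }
  cbind(
    data.frame(run = run, block_index = 1L, block_condition = "none",
               trial_index = seq_len(n), trial_type = types,
               stringsAsFactors = FALSE),
    sternberg_durations(n),
    data.frame(is_match = is_match, is_shock_trial = FALSE)
  )
}

sternberg_threat_session <- function(n_per_type_per_block,
                                     n_runs = 2L, blocks_per_cond = 2L,
                                     shock_trials_per_run = 2L) {
  rows <- list()
  for (r in seq_len(n_runs)) {
    # block order counterbalanced across runs: safe-first then threat-first
    conds <- if (r %% 2L == 1L) c("safe", "threat") else c("threat", "safe")
    order_ <- rep(conds, blocks_per_cond)
    run_rows <- list()
    for (b in seq_along(order_)) {
      types <- sample(rep(c("sort", "maintain"), n_per_type_per_block))
      n <- length(types)
      run_rows[[b]] <- cbind(
        data.frame(run = r, block_index = b, block_condition = order_[b],
                   trial_index = NA_integer_, trial_type = types,
                   stringsAsFactors = FALSE),
        sternberg_durations(n),
        data.frame(is_match = NA, is_shock_trial = FALSE)
      )
    }
    run_df <- do.call(rbind, run_rows)
    # match balance within each trial_type x block_condition cell per run
    for (tt in c("sort", "maintain")) {
      for (bc in c("safe", "threat")) {
        sel <- run_df$trial_type == tt & run_df$block_condition == bc
        run_df$is_match[sel] <- balanced_matches(
          sum(sel), paste(tt, bc, "run", r))
      }
    }
    # extra shock trials inserted at random threat-block positions
    threat_pos <- which(run_df$block_condition == "threat")
    at <- sort(threat_pos[sample.int(length(threat_pos),
                                     shock_trials_per_run)])
    shock_rows <- cbind(
      data.frame(run = r, block_index = run_df$block_index[at],
                 block_condition = "threat", trial_index = NA_integer_,
                 trial_type = sample(c("sort", "maintain"),
                                     shock_trials_per_run, replace = TRUE),
                 stringsAsFactors = FALSE),
      sternberg_durations(shock_trials_per_run),
      data.frame(is_match = sample(c(TRUE, FALSE), shock_trials_per_run,
                                   replace = TRUE),
                 is_shock_trial = TRUE)
    )
    pieces <- list()
    prev <- 0L
    for (k in seq_along(at)) {
      pieces[[length(pieces) + 1L]] <- run_df[(prev + 1L):at[k], , drop = FALSE]
      pieces[[length(pieces) + 1L]] <- shock_rows[k, , drop = FALSE]
      prev <- at[k]
    }
    if (prev < nrow(run_df)) {
      pieces[[length(pieces) + 1L]] <- run_df[(prev + 1L):nrow(run_df), ,
                                              drop = FALSE]
    }
    run_df <- do.call(rbind, pieces)
    run_df$trial_index <- seq_len(nrow(run_df))
    rows[[r]] <- run_df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

add_sternberg_onsets <- function(trials) {
  dur <- trials$instruction_s + trials$letters_s + trials$retention_s +
    trials$probe_s + trials$iti_s
  onset <- numeric(nrow(trials))
  for (r in unique(trials$run)) {
    sel <- trials$run == r
    onset[sel] <- cumsum(c(0, dur[sel]))[seq_len(sum(sel))]
  }
  trials$onset_s <- onset
  trials
}

#' @export
schedule_events.sternberg_schedule <- function(schedule,
                                               subject_id = "sub01",
                                               session = "pretest") {
  tr <- schedule$trials
  event_row(subject_id, session, tr$run, tr$block_index,
            toupper(substr(tr$block_condition, 1, 1)), tr$trial_index,
            tr$trial_type,
            ifelse(tr$is_shock_trial, "shock", "probe"),
            tr$onset_s,
            tr$instruction_s + tr$letters_s + tr$retention_s + tr$probe_s,
            paste(tr$trial_type, tr$block_condition, sep = "_"))
}
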