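#' Build an NPU threat-task schedule
#'
#' Constructs the timed two-run structure of the NPU paradigm: alternating
#' Neutral (N, never at risk of shock), Predictable (P, at risk only during
#' the cue) and Unpredictable (U, at risk throughout) blocks. Each block
#' contains probe trials in two phases — during an 8-s visual cue and during
#' the intertrial interval (ITI) — and every threat block (P or U) is
#' separated from the next threat block by a Neutral block.
#'
#' Per block, Neutral contributes `trials_per_phase["N"]` (default 2) probe
#' trials per phase and P/U contribute 4 per phase, so the default two-run
#' schedule carries 16 trials for each of the six condition labels
#' (`N_cue`, `N_iti`, `P_cue`, `P_iti`, `U_cue`, `U_iti`).
#'
#' Probe placement within intervals is jittered uniformly, constrained so
#' that successive probes are always at least `min_probe_gap_s` apart
#' (avoids probe-on-probe startle refractoriness). Each block is laid out as
#' alternating ITI and cue intervals (one probe each); ITI durations are
#' drawn uniformly from `iti_range_s`.
#'
#' @param order_pair character vector of two 8-letter block orders over
#'   `{N,P,U}`, one per run. Default: the standard counterbalanced pair
#'   `c("NPNUNUNP", "NUNPNPNU")`.
#' @param trial_params list overriding any of: `trials_per_phase` (named
#'   vector, trials per phase for N/P/U blocks), `cue_dur_s` (8),
#'   `iti_range_s` (`c(12, 18)`), `cue_probe_offset_s` (`c(3, 5.5)`, probe
#'   jitter window inside the cue), `iti_probe_margin_s` (`c(6, 5)`:
#'   probe no earlier than 6 s into the ITI and no later than 5 s before
#'   its end), `min_probe_gap_s` (8).
#' @param rng_seed integer seed for the jitter; `NULL` uses the current RNG.
#' @return An object of class `npu_schedule`: list with `trials` (one row
#'   per probe trial: run, block_index, block_type, trial_index, phase,
#'   interval_onset_s, interval_dur_s, probe_time_s, condition_label),
#'   `shocks` (empty until [place_shocks()]), and `params`.
#' @seealso [place_shocks()], [schedule_events()]
#' @examples
#' sch <- build_npu_schedule(rng_seed = 1)
#' table(sch$trials$condition_label)
#' @export
build_npu_schedule <- function(order_pair = c("NPNUNUNP", "NUNPNPNU"),
                               trial_params = list(),
                               rng_seed = NULL) {
  defaults <- list(
    trials_per_phase = c(N = 2, P = 4, U = 4),
    cue_dur_s = 8,
    iti_range_s = c(12, 18),
    cue_probe_offset_s = c(3, 5.5),
    iti_probe_margin_s = c(6, 5),
    min_probe_gap_s = 8
  )
  p <- utils::modifyList(defaults, trial_params)

  if (length(order_pair) != 2L) {
    stop_npu("`order_pair` must contain exactly two block orders (one per run)")
  }
  orders <- lapply(order_pair, parse_npu_order)

  if (p$iti_range_s[1] < sum(p$iti_probe_margin_s)) {
    stop_npu("ITI range too short for the configured probe margins")
  }

  trials <- with_seed(rng_seed, {
    runs <- lapply(seq_along(orders), function(r) {
      layout_npu_run(orders[[r]], r, p)
    })
    do.call(rbind, runs)
  })
  rownames(trials) <- NULL

  structure(
    list(trials = trials,
         shocks = empty_shock_table(),
         order_pair = order_pair,
         params = p),
    class = "npu_schedule"
  )
}

parse_npu_order <- function(order) {
  letters_ <- strsplit(order, "")[[1]]
  if (length(letters_) != 8L) {
    stop_npu("block order '", order, "' must have exactly 8 blocks")
  }
  if (!all(letters_ %in% c("N", "P", "U"))) {
    stop_npu("block order '", order, "' contains letters outside {N,P,U}")
  }
  threat <- letters_ %in% c("P", "U")
  if (any(threat[-8] & threat[-1])) {
    stop_npu("block order '", order,
             "' has adjacent threat blocks; P and U must be separated by N")
  }
  letters_
}

layout_npu_run <- function(block_types, run, p) {
  t <- 0
  rows <- list()
  trial_index <- 0L
  for (b in seq_along(block_types)) {
    btype <- block_types[b]
    n_pairs <- p$trials_per_phase[[btype]]
    for (k in seq_len(n_pairs)) {
      iti_dur <- stats::runif(1, p$iti_range_s[1], p$iti_range_s[2])
      iti_probe <- t + stats::runif(1, p$iti_probe_margin_s[1],
                                    iti_dur - p$iti_probe_margin_s[2])
      trial_index <- trial_index + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        run = run, block_index = b, block_type = btype,
        trial_index = trial_index, phase = "iti",
        interval_onset_s = t, interval_dur_s = iti_dur,
        probe_time_s = iti_probe,
        condition_label = paste0(btype, "_iti"),
        stringsAsFactors = FALSE
      )
      t <- t + iti_dur
      cue_probe <- t + stats::runif(1, p$cue_probe_offset_s[1],
                                    p$cue_probe_offset_s[2])
      trial_index <- trial_index + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        run = run, block_index = b, block_type = btype,
        trial_index = trial_index, phase = "cue",
        interval_onset_s = t, interval_dur_s = p$cue_dur_s,
        probe_time_s = cue_probe,
        condition_label = paste0(btype, "_cue"),
        stringsAsFactors = FALSE
      )
      t <- t + p$cue_dur_s
    }
  }
  do.call(rbind, rows)
}

empty_shock_table <- function() {
  data.frame(run = integer(), block_index = integer(),
             trial_index = integer(), condition_label = character(),
             time_s = numeric(), stringsAsFactors = FALSE)
}

#' Attach shock events to an NPU schedule
#'
#' Places `n_per_run` shocks per run, each in a uniformly chosen eligible
#' interval: the cue of a Predictable trial, or any interval (cue or ITI)
#' of an Unpredictable block. Neutral blocks never receive shocks. No two
#' shocks share a trial; the shock time falls inside the chosen interval,
#' at least 1 s after its probe.
#'
#' @param schedule an `npu_schedule` from [build_npu_schedule()].
#' @param n_per_run number of shocks per run (default 3).
#' @param rng_seed integer seed; `NULL` uses the current RNG.
#' @return The schedule with its `shocks` table filled.
#' @export
place_shocks <- function(schedule, n_per_run = 3, rng_seed = NULL) {
  stopifnot(inherits(schedule, "npu_schedule"))
  if (n_per_run < 0) stop_npu("`n_per_run` must be >= 0")
  trials <- schedule$trials
  eligible <- (trials$block_type == "P" & trials$phase == "cue") |
    trials$block_type == "U"

  shocks <- with_seed(rng_seed, {
    out <- list()
    for (r in unique(trials$run)) {
      idx <- which(eligible & trials$run == r)
      if (length(idx) < n_per_run) {
        stop_npu("run ", r, ": only ", length(idx),
                 " eligible intervals for ", n_per_run, " shocks")
      }
      if (n_per_run == 0) next
      chosen <- sort(idx[sample.int(length(idx), n_per_run)])
      tr <- trials[chosen, ]
      times <- stats::runif(n_per_run, tr$probe_time_s + 1,
                            tr$interval_onset_s + tr$interval_dur_s)
      out[[length(out) + 1L]] <- data.frame(
        run = tr$run, block_index = tr$block_index,
        trial_index = tr$trial_index,
        condition_label = tr$condition_label,
        time_s = times, stringsAsFactors = FALSE
      )
    }
    if (length(out)) do.call(rbind, out) else empty_shock_table()
  })
  rownames(shocks) <- NULL
  schedule$shocks <- shocks
  schedule
}

#' Build a startle-habituation probe schedule
#'
#' An initial series of unsignaled white-noise probes used to stabilize
#' startle magnitude before the task: `n_probes` probes spaced near
#' `mean_isi_s` apart with uniform jitter of up to `jitter_s`.
#'
#' @param n_probes number of probes (default 9).
#' @param mean_isi_s mean inter-probe interval in seconds (default 17).
#' @param jitter_s half-width of the uniform jitter band (default 1.5).
#' @param start_s time of the first probe (default 0).
#' @param rng_seed integer seed; `NULL` uses the current RNG.
#' @return An object of class `habituation_schedule` with `probe_times_s`.
#' @export
build_habituation_schedule <- function(n_probes = 9, mean_isi_s = 17,
                                       jitter_s = 1.5, start_s = 0,
                                       rng_seed = NULL) {
  if (n_probes < 1) stop_npu("`n_probes` must be >= 1")
  if (mean_isi_s <= 0) stop_npu("`mean_isi_s` must be positive")
  if (jitter_s < 0) stop_npu("`jitter_s` must be nonnegative")
  if (mean_isi_s - jitter_s <= 0) {
    stop_npu("jitter band must keep inter-probe intervals positive")
  }
  gaps <- with_seed(rng_seed, {
    if (n_probes == 1L) numeric(0)
    else stats::runif(n_probes - 1L, mean_isi_s - jitter_s,
                      mean_isi_s + jitter_s)
  })
  structure(
    list(probe_times_s = start_s + cumsum(c(0, gaps)),
         mean_isi_s = mean_isi_s, jitter_s = jitter_s),
    class = "habituation_schedule"
  )
}

#' Flatten a schedule to a standard event table
#'
#' Serializes any schedule built by this package to the columnar event
#' format shared by the whole pipeline: one row per probe / shock / pulse
#' with onset in seconds from run start.
#'
#' @param schedule an `npu_schedule`, `habituation_schedule`,
#'   `sternberg_schedule` or `pulse_train_schedule`.
#' @param subject_id,session identifiers stamped on every row.
#' @return data.frame with columns subject_id, session, run, block_index,
#'   block_type, trial_index, phase, event_type, onset_s, duration_s,
#'   condition_label.
#' @export
schedule_events <- function(schedule, subject_id = "sub01",
                            session = "pretest") {
  UseMethod("schedule_events")
}

event_row <- function(subject_id, session, run, block_index, block_type,
                      trial_index, phase, event_type, onset_s, duration_s,
                      condition_label) {
  data.frame(subject_id = subject_id, session = session, run = run,
             block_index = block_index, block_type = block_type,
             trial_index = trial_index, phase = phase,
             event_type = event_type, onset_s = onset_s,
             duration_s = duration_s, condition_label = condition_label,
             stringsAsFactors = FALSE)
}

#' @export
schedule_events.npu_schedule <- function(schedule, subject_id = "sub01",
                                         session = "pretest") {
  tr <- schedule$trials
  probes <- event_row(subject_id, session, tr$run, tr$block_index,
                      tr$block_type, tr$trial_index, tr$phase, "probe",
                      tr$probe_time_s, 0.040, tr$condition_label)
  ev <- probes
  if (nrow(schedule$shocks)) {
    sh <- schedule$shocks
    bt <- substr(sh$condition_label, 1, 1)
    ph <- sub("^[NPU]_", "", sh$condition_label)
    shocks <- event_row(subject_id, session, sh$run, sh$block_index, bt,
                        sh$trial_index, ph, "shock", sh$time_s, 0.100,
                        sh$condition_label)
    ev <- rbind(ev, shocks)
  }
  ev <- ev[order(ev$run, ev$onset_s), ]
  rownames(ev) <- NULL
  ev
}

#' @export
schedule_events.habituation_schedule <- function(schedule,
                                                 subject_id = "sub01",
                                                 session = "pretest") {
  n <- length(schedule$probe_times_s)
  event_row(subject_id, session, 1L, 1L, "HAB", seq_len(n), "iti", "probe",
            schedule$probe_times_s, 0.040, "HAB")
}
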