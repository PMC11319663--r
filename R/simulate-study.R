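#' Study-level effect specification
#'
#' Population parameters for a crossover startle study: every subject is
#' measured under an active and a sham stimulation session, and each
#' session yields fear-potentiated (FPS) and anxiety-potentiated (APS_ITI)
#' difference scores for startle (t-score scale) and anxiety ratings
#' (0–10 scale).
#'
#' Effect sizes are standardized on the per-subject contrast that the
#' downstream 2x2 ANOVA tests: `coil_effect_d` is the paired-d of the
#' active − sham contrast (applied equally to FPS and APS, i.e. no
#' coil-by-response-type interaction), and `response_type_effect_d` the
#' paired-d of the FPS − APS contrast. Ratings carry a response-type
#' effect but no coil effect (sham-indistinguishable by design); its
#' default is negative because subjects typically report larger anxiety
#' increases under unpredictable threat (APS) than to the predictable cue
#' (FPS), while startle shows the opposite ordering.
#'
#' @param n_subjects number of subjects (>= 2; default 28).
#' @param coil_effect_d standardized active − sham effect on startle
#'   difference scores.
#' @param response_type_effect_d standardized FPS − APS effect on startle.
#' @param aps_mean population APS_ITI mean on the t-score scale.
#' @param between_subject_sd SD of the subject random effect (t-units).
#' @param within_cell_sd SD of the session-by-score residual (t-units).
#' @param ratings_response_type_d,ratings_aps_mean,ratings_between_sd,ratings_within_sd
#'   analogous parameters for the ratings difference scores (0–10 scale).
#' @param coil_potentiation_boost for the raw-EMG path only
#'   ([simulate_study()]): fractional boost of the condition potentiation
#'   (multiplier − 1) in active sessions. Because t-scoring renormalizes
#'   each session, a coil effect must alter *relative* potentiation, not
#'   overall gain, to survive scoring.
#' @param rng_seed integer seed; `NULL` uses the current RNG.
#' @return list of class `study_effect_spec`.
#' @export
study_effect_spec <- function(n_subjects = 28, coil_effect_d = 0,
                              response_type_effect_d = 0.61,
                              aps_mean = 5, between_subject_sd = 8,
                              within_cell_sd = 5,
                              ratings_response_type_d = -1.29,
                              ratings_aps_mean = 2.5,
                              ratings_between_sd = 1,
                              ratings_within_sd = 0.8,
                              coil_potentiation_boost = 0.15,
                              rng_seed = NULL) {
  vals <- mget(names(formals()), environment())
  if (n_subjects < 2) stop_npu("`n_subjects` must be >= 2")
  for (s in c(between_subject_sd, within_cell_sd, ratings_between_sd,
              ratings_within_sd)) {
    if (s <= 0) stop_npu("all standard deviations must be positive")
  }
  structure(vals, class = "study_effect_spec")
}

#' Simulate difference-score outcomes for a crossover startle study
#'
#' Draws the per-subject outcome table directly on the analysis scale
#' (startle t-scores, ratings points), bypassing raw-EMG synthesis: cell
#' value = score-type mean + subject random effect + coil shift +
#' independent residual. This is the generator used for statistical
#' calibration, where thousands of replicate studies are needed; the
#' standardized effects it realizes are exact by construction (see
#' [study_effect_spec()]).
#'
#' @param spec a [study_effect_spec()].
#' @return data.frame of class `outcome_draws`: subject_id, coil
#'   (`active` / `sham`), measure (`startle_t` / `rating`), score_type
#'   (`FPS` / `APS_ITI`), value.
#' @export
simulate_study_outcomes <- function(spec = study_effect_spec()) {
  stopifnot(inherits(spec, "study_effect_spec"))
  with_seed(spec$rng_seed, {
    n <- spec$n_subjects
    subj <- sprintf("sub%02d", seq_len(n))
    grid <- expand.grid(subject_id = subj, coil = c("active", "sham"),
                        score_type = c("FPS", "APS_ITI"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

    startle <- grid
    b <- stats::rnorm(n, 0, spec$between_subject_sd)
    names(b) <- subj
    mu <- spec$aps_mean +
      (startle$score_type == "FPS") *
        spec$response_type_effect_d * spec$within_cell_sd +
      (startle$coil == "active") *
        spec$coil_effect_d * spec$within_cell_sd
    startle$measure <- "startle_t"
    startle$value <- mu + b[startle$subject_id] +
      stats::rnorm(nrow(startle), 0, spec$within_cell_sd)

    ratings <- grid
    br <- stats::rnorm(n, 0, spec$ratings_between_sd)
    names(br) <- subj
    mur <- spec$ratings_aps_mean +
      (ratings$score_type == "FPS") *
        spec$ratings_response_type_d * spec$ratings_within_sd
    ratings$measure <- "rating"
    ratings$value <- mur + br[ratings$subject_id] +
      stats::rnorm(nrow(ratings), 0, spec$ratings_within_sd)

    out <- rbind(startle, ratings)[, c("subject_id", "coil", "measure",
                                       "score_type", "value")]
    class(out) <- c("outcome_draws", class(out))
    out
  })
}

#' Simulate a full raw-EMG crossover study
#'
#' Generates continuous EMG recordings plus trial ratings for
#' `n_subjects x {active, sham}` sessions. Each session draws a fresh NPU
#' schedule, a subject-level amplitude random effect, and — in active
#' sessions — a potentiation boost of `coil_potentiation_boost` on every
#' condition multiplier's excess over 1 (see [study_effect_spec()] for why
#' the coil effect must be relative). Per-session seeds are derived
#' deterministically from `spec$rng_seed`, the subject id and the session
#' label.
#'
#' @param spec a [study_effect_spec()]; `n_subjects`, `coil_effect_d`
#'   (only its sign/presence via the boost), `rng_seed` are used.
#' @param blink a [blink_sim_params()] giving the per-trial EMG model.
#' @param rating_condition_means named per-condition rating means (0–10).
#' @param rating_sd trial rating noise SD (truncated to [0, 10]).
#' @return list with `recordings` (list of `emg_recording`), `ratings`
#'   (long data.frame), `ground_truth` (row-bound per-trial truth),
#'   `spec`.
#' @export
simulate_study <- function(spec = study_effect_spec(),
                           blink = blink_sim_params(),
                           rating_condition_means = c(
                             N_cue = 1.5, N_iti = 1.5,
                             P_cue = 4.0, P_iti = 2.0,
                             U_cue = 4.5, U_iti = 4.0),
                           rating_sd = 1.0) {
  stopifnot(inherits(spec, "study_effect_spec"),
            inherits(blink, "blink_sim_params"))
  seed0 <- spec$rng_seed %||% sample.int(2^31 - 1, 1)
  subj <- sprintf("sub%02d", seq_len(spec$n_subjects))
  recs <- list()
  ratings <- list()
  truth <- list()
  for (s in subj) {
    subj_gain <- with_seed(derive_seed(seed0, s, "subject"),
                           exp(stats::rnorm(1, 0, 0.2)))
    for (ses in c("active", "sham")) {
      sd_ses <- derive_seed(seed0, s, ses)
      boost <- if (ses == "active") 1 + spec$coil_potentiation_boost else 1
      mult <- 1 + (blink$condition_multipliers - 1) * boost
      p <- blink
      p$base_amplitude_uv <- blink$base_amplitude_uv * subj_gain
      p$condition_multipliers <- mult
      p$rng_seed <- derive_seed(sd_ses, "emg")
      sch <- build_npu_schedule(rng_seed = derive_seed(sd_ses, "schedule"))
      sch <- place_shocks(sch, 3, rng_seed = derive_seed(sd_ses, "shock"))
      rec <- simulate_session(sch, p, subject_id = s, session_label = ses)
      recs[[paste(s, ses, sep = "_")]] <- rec

      gt <- rec$ground_truth
      r <- with_seed(derive_seed(sd_ses, "ratings"), {
        m <- rating_condition_means[gt$condition_label]
        m[is.na(m)] <- 0
        pmin(10, pmax(0, stats::rnorm(nrow(gt), m, rating_sd)))
      })
      ratings[[paste(s, ses, sep = "_")]] <- data.frame(
        subject_id = s, session = ses, run = gt$run,
        trial_index = gt$trial_index,
        condition_label = gt$condition_label,
        rating = as.numeric(r), status = "valid",
        stringsAsFactors = FALSE
      )
      truth[[paste(s, ses, sep = "_")]] <- gt
    }
  }
  list(recordings = recs,
       ratings = do.call(rbind, c(ratings, list(make.row.names = FALSE))),
       ground_truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       spec = spec)
}
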