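# Shared fixture builders. Everything is generated in code at test time.

# A short habituation-style recording with known blink amplitudes.
quick_session <- function(n_probes = 9, noise_sd = 0, seed = 1,
                          artifact_prob = 0, no_blink_prob = 0,
                          multipliers = NULL) {
  params <- blink_sim_params(
    baseline_noise_sd_uv = noise_sd,
    artifact_prob = artifact_prob,
    no_blink_prob = no_blink_prob,
    rng_seed = seed
  )
  if (!is.null(multipliers)) params$condition_multipliers <- multipliers
  sch <- build_habituation_schedule(n_probes = n_probes,
                                    rng_seed = seed + 1000)
  simulate_session(sch, params)
}

# Brute-force trial scoring straight off a stored envelope, using the
# same index arithmetic as the scoring contract but none of its code
# paths beyond the envelope itself.
brute_force_score <- function(envelope, onset_s, fs = 2000) {
  i0 <- floor(onset_s * fs + 0.5)
  base <- envelope[(i0 - floor(0.050 * fs + 0.5) + 1):i0]
  peak <- max(envelope[(i0 + floor(0.020 * fs + 0.5) + 1):
                         (i0 + floor(0.120 * fs + 0.5) + 1)])
  peak - mean(base)
}

# Long-format 2x2 within-subject dataset with random cell values.
random_2x2 <- function(n, seed) {
  set.seed(seed)
  d <- expand.grid(subject_id = sprintf("s%02d", seq_len(n)),
                   coil = c("active", "sham"),
                   score_type = c("FPS", "APS_ITI"),
                   stringsAsFactors = FALSE)
  d$value <- stats::rnorm(nrow(d), sd = 2) +
    rep(stats::rnorm(n, sd = 3), 4)
  d
}
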