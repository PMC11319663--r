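cfg <- scoring_config()

test_that("envelope extraction: linearity, zero input, band selectivity", {
  expect_equal(preprocess_emg(numeric(4000), cfg), numeric(4000))
  # homogeneity: scaling the input scales the envelope exactly
  set.seed(1)
  x <- rnorm(6000)
  expect_equal(preprocess_emg(3.5 * x, cfg), 3.5 * preprocess_emg(x, cfg))
  # out-of-band 10 Hz tone attenuated >= 20 dB relative to 100 Hz tone
  t <- seq_len(8000) / 2000
  env_low <- preprocess_emg(sin(2 * pi * 10 * t), cfg)
  env_mid <- preprocess_emg(sin(2 * pi * 100 * t), cfg)
  mid <- 2000:6000
  rms <- function(v) sqrt(mean(v^2))
  expect_gt(20 * log10(rms(env_mid[mid]) / rms(env_low[mid])), 20)
  # sampling rate too low for the band
  expect_error(scoring_config(fs_hz = 500), "Nyquist")
})

test_that("adding a DC offset leaves raw amplitudes unchanged", {
  rec <- quick_session(n_probes = 5, noise_sd = 1, seed = 2)
  shifted <- rec
  shifted$samples <- shifted$samples + 100
  s0 <- score_recording(rec, cfg)
  s1 <- score_recording(shifted, cfg)
  expect_equal(s1$raw_uv, s0$raw_uv, tolerance = 1e-6)
})

test_that("score_trial window arithmetic on constructed envelopes", {
  fs <- 2000
  # flat envelope: peak equals baseline, raw 0
  flat <- rep(4.2, 2000)
  sc <- score_trial(flat, 0.5, cfg)
  expect_equal(sc$raw_uv, 0)
  # triangular bump of height h at onset + 60 ms over zero baseline
  env <- numeric(3000)
  onset <- 1.0
  apex <- round(onset * fs) + round(0.060 * fs)
  h <- 7.5
  ramp <- seq(0, h, length.out = 21)
  env[(apex - 20):(apex + 20) + 1] <- c(ramp, rev(ramp)[-1])
  expect_equal(score_trial(env, onset, cfg)$raw_uv, h)
  # windows out of range are reported with the trial onset
  expect_error(score_trial(numeric(100), 0.01, cfg), "outside")
})

test_that("trial scores equal brute-force window max-minus-mean", {
  rec <- quick_session(n_probes = 9, noise_sd = 1.5, seed = 3)
  env <- preprocess_emg(rec, cfg)
  sc <- score_recording(rec, cfg)
  probes <- rec$events[rec$events$event_type == "probe", ]
  oracle <- vapply(probes$onset_s, function(on)
    brute_force_score(env, on), numeric(1))
  valid <- sc$status == "valid"
  expect_equal(sc$raw_uv[valid], oracle[valid], tolerance = 1e-12)
})

test_that("noisy-trial flagging catches an amplified baseline", {
  # one artifact-amplified trial over 16 quiet ones
  params <- blink_sim_params(baseline_noise_sd_uv = 2, rng_seed = 4)
  sch <- build_habituation_schedule(n_probes = 17, rng_seed = 5)
  rec <- simulate_session(sch, params)
  art <- 7L  # amplify the 7th trial's pre-probe noise tenfold
  i0 <- round(rec$ground_truth$probe_onset_s[art] * rec$fs_hz)
  idx <- (i0 - 500):i0
  rec$samples[idx] <- rec$samples[idx] * 10
  sc <- score_recording(rec, cfg)
  expect_equal(which(sc$status == "missing_noisy"), art)
  # brute-force recomputation of the flag decision
  env <- preprocess_emg(rec, cfg)
  base_sds <- vapply(sc$probe_onset_s, function(on) {
    i0 <- round(on * 2000)
    sd(env[(i0 - 99):i0])
  }, numeric(1))
  centered <- lapply(sc$probe_onset_s, function(on) {
    i0 <- round(on * 2000)
    w <- env[(i0 - 99):i0]
    w - mean(w)
  })
  run_sd <- sd(unlist(centered))
  expect_equal(sc$status == "missing_noisy", base_sds > 2 * run_sd)
})

test_that("flag monotonicity: higher multiplier never flags more trials", {
  params <- blink_sim_params(baseline_noise_sd_uv = 2, artifact_prob = 0.2,
                             rng_seed = 6)
  sch <- build_habituation_schedule(n_probes = 12, rng_seed = 7)
  rec <- simulate_session(sch, params)
  counts <- vapply(c(0.5, 1, 2, 4, 1e9), function(k) {
    ck <- scoring_config(noise_multiplier = k)
    sum(score_recording(rec, ck)$status == "missing_noisy")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 0)
})

test_that("no-blink coding rules on constructed trial tables", {
  base <- data.frame(
    subject_id = "s", session = "pretest", run = 1, trial_index = 1:3,
    raw_uv = c(5, 0.4, 3), baseline_mean_uv = c(1, 1, 0),
    baseline_sd_uv = 0.1, baseline_range_uv = c(0.5, 1.2, 0),
    peak_uv = c(6, 1.4, 3), status = "valid"
  )
  coded <- code_no_blink(base, cfg)
  # trial 2: peak 1.4 <= 1 + 1.2 -> coded 0; trial 3: range 0, positive peak
  expect_equal(coded$status, c("valid", "zero_no_blink", "valid"))
  expect_equal(coded$raw_uv, c(5, 0, 3))
  # literal range-only reading
  lit <- code_no_blink(base, scoring_config(no_blink_rule = "range_only"))
  expect_equal(lit$status, c("valid", "valid", "valid"))
  # missing trials are never re-coded
  base$status[2] <- "missing_noisy"
  expect_equal(code_no_blink(base, cfg)$status[2], "missing_noisy")
})

test_that("t-normalization: frozen example, group mean 50 and SD 10", {
  tr <- data.frame(subject_id = "s", session = "pretest", run = 1,
                   trial_index = 1:3, raw_uv = c(1, 2, 3),
                   status = "valid")
  out <- t_normalize(tr)
  expect_equal(out$t, c(40, 50, 60))
  expect_equal(out$z, c(-1, 0, 1))
  # property over random groups
  for (seed in 1:5) {
    set.seed(seed)
    tr <- data.frame(subject_id = "s", session = "a", run = 1,
                     trial_index = 1:20, raw_uv = rexp(20) * 50,
                     status = sample(c("valid", "missing_noisy"), 20,
                                     replace = TRUE, prob = c(0.8, 0.2)))
    out <- t_normalize(tr)
    ok <- out$status != "missing_noisy"
    expect_equal(mean(out$t[ok]), 50)
    expect_equal(sd(out$t[ok]), 10)
    expect_true(all(is.na(out$t[!ok])))
  }
  # degenerate groups are rejected with the group named
  one <- data.frame(subject_id = "solo", session = "a", run = 1,
                    trial_index = 1, raw_uv = 1, status = "valid")
  expect_error(t_normalize(one), "solo")
  const <- data.frame(subject_id = "flat", session = "a", run = 1,
                      trial_index = 1:4, raw_uv = rep(2, 4),
                      status = "valid")
  expect_error(t_normalize(const), "zero variance")
})

test_that("scoring pipeline is deterministic for identical input", {
  rec <- quick_session(n_probes = 6, noise_sd = 1, seed = 8)
  expect_identical(score_recording(rec, cfg), score_recording(rec, cfg))
})
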