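test_that("NPU builder yields the printed design counts", {
  sch <- build_npu_schedule(rng_seed = 1)
  counts <- table(sch$trials$condition_label)
  expect_setequal(names(counts),
                  c("N_cue", "N_iti", "P_cue", "P_iti", "U_cue", "U_iti"))
  expect_true(all(counts == 16))
  # one run with order NPNUNUNP: block multiset {4 N, 2 P, 2 U}
  run1 <- sch$trials[sch$trials$run == 1, ]
  blocks <- unique(run1[, c("block_index", "block_type")])
  expect_equal(sort(table(blocks$block_type), decreasing = TRUE),
               sort(c(N = 4, P = 2, U = 2), decreasing = TRUE),
               ignore_attr = TRUE)
  # N-block probe trials per run: 4 blocks x 2 phases x 2 trials
  expect_equal(sum(run1$block_type == "N"), 16)
})

test_that("NPU probe times are increasing and respect the refractory gap", {
  for (seed in 1:5) {
    sch <- build_npu_schedule(rng_seed = seed)
    for (r in 1:2) {
      pt <- sch$trials$probe_time_s[sch$trials$run == r]
      expect_true(all(diff(pt) > 0))
      expect_true(all(diff(pt) >= 8 - 1e-9))
    }
    # probes fall inside their own interval
    with(sch$trials, {
      expect_true(all(probe_time_s >= interval_onset_s))
      expect_true(all(probe_time_s <= interval_onset_s + interval_dur_s))
    })
  }
})

test_that("NPU builder rejects malformed block orders", {
  expect_error(build_npu_schedule(c("NPUNUNUN", "NUNPNPNU")), "adjacent")
  expect_error(build_npu_schedule(c("NPNUNUN", "NUNPNPNU")), "8 blocks")
  expect_error(build_npu_schedule(c("NPNXNUNP", "NUNPNPNU")), "outside")
  expect_error(build_npu_schedule("NPNUNUNP"), "two block orders")
})

test_that("schedules rebuild bit-identically from the same seed", {
  expect_identical(build_npu_schedule(rng_seed = 7),
                   build_npu_schedule(rng_seed = 7))
  expect_identical(build_habituation_schedule(rng_seed = 3),
                   build_habituation_schedule(rng_seed = 3))
  expect_identical(build_sternberg_schedule("testing_threat", rng_seed = 5),
                   build_sternberg_schedule("testing_threat", rng_seed = 5))
  a <- place_shocks(build_npu_schedule(rng_seed = 7), 3, rng_seed = 9)
  b <- place_shocks(build_npu_schedule(rng_seed = 7), 3, rng_seed = 9)
  expect_identical(a, b)
})

test_that("shock placement count, eligibility and edge cases", {
  sch <- build_npu_schedule(rng_seed = 2)
  shocked <- place_shocks(sch, 3, rng_seed = 4)
  expect_equal(as.vector(table(shocked$shocks$run)), c(3, 3))
  # shocks only in P-cue or U intervals
  expect_true(all(shocked$shocks$condition_label %in%
                    c("P_cue", "U_cue", "U_iti")))
  # no two shocks share a trial
  expect_false(any(duplicated(
    shocked$shocks[, c("run", "trial_index")])))
  # shock times inside their interval
  tr <- merge(shocked$shocks, sch$trials,
              by = c("run", "block_index", "trial_index"))
  expect_true(all(tr$time_s >= tr$interval_onset_s &
                    tr$time_s <= tr$interval_onset_s + tr$interval_dur_s))
  # zero case leaves the schedule unchanged apart from empty shocks
  zero <- place_shocks(sch, 0, rng_seed = 4)
  expect_identical(zero$trials, sch$trials)
  expect_equal(nrow(zero$shocks), 0)
  # too many shocks for the eligible slots
  expect_error(place_shocks(sch, 100, rng_seed = 1), "eligible")
})

test_that("shock placement is uniform over eligible intervals", {
  sch <- build_npu_schedule(rng_seed = 11)
  eligible <- which((sch$trials$block_type == "P" &
                       sch$trials$phase == "cue") |
                      sch$trials$block_type == "U")
  key <- paste(sch$trials$run, sch$trials$trial_index)
  hits <- integer(length(eligible))
  names(hits) <- key[eligible]
  for (s in 1:1000) {
    sh <- place_shocks(sch, 3, rng_seed = s)$shocks
    k <- paste(sh$run, sh$trial_index)
    hits[k] <- hits[k] + 1L
  }
  expect_equal(sum(hits), 6000)
  gof <- suppressWarnings(stats::chisq.test(hits))
  expect_gt(gof$p.value, 0.01)
})

test_that("habituation schedule counts and jitter band", {
  hab <- build_habituation_schedule(rng_seed = 1)
  expect_length(hab$probe_times_s, 9)
  gaps <- diff(hab$probe_times_s)
  expect_true(all(gaps >= 17 - 1.5 & gaps <= 17 + 1.5))
  # degenerate single probe at the configured start
  expect_equal(build_habituation_schedule(n_probes = 1)$probe_times_s, 0)
  # zero jitter gives exact spacing
  fixed <- build_habituation_schedule(jitter_s = 0)
  expect_equal(diff(fixed$probe_times_s), rep(17, 8))
  expect_error(build_habituation_schedule(jitter_s = -1), "nonneg")
  expect_error(build_habituation_schedule(mean_isi_s = 0), "positive")
})
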