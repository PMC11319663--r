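make_trials <- function(t_by_cond, subject = "s01", session = "active",
                        status = NULL) {
  conds <- rep(names(t_by_cond), lengths(t_by_cond))
  vals <- unlist(t_by_cond, use.names = FALSE)
  data.frame(subject_id = subject, session = session,
             trial_index = seq_along(vals), condition_label = conds,
             t = vals,
             status = status %||% rep("valid", length(vals)),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

six <- c("N_cue", "N_iti", "P_cue", "P_iti", "U_cue", "U_iti")

test_that("condition means average non-missing trials only", {
  cells <- setNames(lapply(six, function(x) rep(55, 16)), six)
  tab <- condition_means(make_trials(cells), "startle_t")
  expect_true(all(tab[, six] == 55))
  expect_true(all(tab[, paste0("n_valid_", six)] == 16))
  # two trials flagged missing: mean over the remaining 14
  cells$U_iti <- c(rep(50, 14), 999, 999)
  tr <- make_trials(cells)
  tr$status[tr$condition_label == "U_iti"][15:16] <- "missing_noisy"
  tab <- condition_means(tr, "startle_t")
  expect_equal(tab$U_iti, 50)
  expect_equal(tab$n_valid_U_iti, 14)
  # subject-session without valid trials in a condition is dropped
  tr2 <- tr[tr$condition_label != "P_cue", ]
  tr2b <- make_trials(cells, subject = "s02")
  expect_warning(tab2 <- condition_means(rbind(tr2, tr2b), "startle_t"),
                 "P_cue")
  expect_equal(tab2$subject_id, "s02")
  expect_error(condition_means(tr[0, ], "startle_t"), "empty")
})

test_that("FPS and APS difference scores", {
  cells <- list(N_cue = 50, N_iti = 48, P_cue = 60, P_iti = 50,
                U_cue = 58, U_iti = 48)
  tab <- difference_scores(condition_means(
    make_trials(lapply(cells, rep, 4)), "startle_t"))
  expect_equal(tab$FPS, 10)     # P_cue - P_iti
  expect_equal(tab$APS_ITI, 0)  # U_iti - N_iti
  # missing required condition is named
  broken <- tab[, setdiff(names(tab), "U_iti")]
  expect_error(difference_scores(broken), "U_iti")
})

test_that("difference scores are invariant to per-subject constants", {
  cells <- setNames(lapply(six, function(x) rnorm(8, 55, 5)), six)
  tr <- make_trials(cells)
  shifted <- tr
  shifted$t <- shifted$t + 12.3
  a <- difference_scores(condition_means(tr, "startle_t"))
  b <- difference_scores(condition_means(shifted, "startle_t"))
  expect_equal(a$FPS, b$FPS)
  expect_equal(a$APS_ITI, b$APS_ITI)
})

test_that("outlier truncation: frozen example and contracts", {
  v <- c(0, 0, 0, 0, 0, 0, 0, 8)
  out <- truncate_outliers(v)
  expect_equal(out, c(rep(0, 7), 1 + 2 * sqrt(8)), tolerance = 1e-12)
  expect_equal(out[8], 6.65685424949238, tolerance = 1e-10)
  # vectors already inside the bounds pass through untouched
  w <- seq(-1, 1, length.out = 20)  # max |z| well below 2
  expect_identical(truncate_outliers(w), w)
  # single-pass contract: bounds come from the ORIGINAL moments; the
  # clamped vector has new moments, so re-application would move values
  # again — the pipeline must (and does) apply truncation exactly once
  expect_equal(out[8], mean(v) + 2 * sd(v))
  expect_false(isTRUE(all.equal(truncate_outliers(out), out)))
  # sign of deviation never flips, values never cross the far bound
  set.seed(2)
  for (i in 1:20) {
    x <- rt(12, df = 2) * 10
    y <- truncate_outliers(x)
    expect_true(all(sign(y - mean(x)) %in% c(0, sign(x - mean(x)))))
    expect_true(all(y >= mean(x) - 2 * sd(x) - 1e-12))
    expect_true(all(y <= mean(x) + 2 * sd(x) + 1e-12))
  }
  # constant vectors are returned unchanged
  expect_identical(truncate_outliers(rep(3, 5)), rep(3, 5))
})

test_that("vectors of five or fewer values are never truncated at k = 2", {
  # max standardized deviation with sample SD is (n-1)/sqrt(n) < 2 for n <= 5
  set.seed(3)
  for (n in 2:5) {
    for (i in 1:50) {
      x <- rcauchy(n) * 100
      expect_identical(truncate_outliers(x), x)
    }
  }
})

test_that("behavior aggregation: cell means, shock discard, WM scores", {
  grid <- expand.grid(trial = 1:12, trial_type = c("sort", "maintain"),
                      block_condition = c("safe", "threat"),
                      stringsAsFactors = FALSE)
  resp <- data.frame(subject_id = "s01", session = "active",
                     trial_type = grid$trial_type,
                     block_condition = grid$block_condition,
                     is_shock_trial = FALSE,
                     correct = TRUE, rt_s = 0.8)
  # 9 of 12 correct in one cell -> 75%
  sel <- resp$trial_type == "sort" & resp$block_condition == "threat"
  resp$correct[which(sel)[1:3]] <- FALSE
  # shock trials must not contaminate the means
  shock <- resp[1:2, ]
  shock$is_shock_trial <- TRUE
  shock$correct <- FALSE
  shock$rt_s <- 9
  agg <- behavior_aggregate(rbind(resp, shock))
  cells <- agg$cells
  expect_equal(cells$percent_correct[cells$trial_type == "sort" &
                                       cells$block_condition == "threat"],
               75)
  expect_true(all(cells$percent_correct[cells$trial_type == "maintain"] ==
                    100))
  expect_true(all(cells$mean_rt_s == 0.8))
  # identical RTs give a zero WM difference score
  expect_equal(agg$wm_difference$wm_rt_s, c(0, 0))
  expect_equal(
    agg$wm_difference$wm_percent_correct[
      agg$wm_difference$block_condition == "threat"], -25)
  expect_error(behavior_aggregate(resp[0, ]), "empty")
})
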