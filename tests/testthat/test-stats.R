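test_that("each main-effect F equals the squared paired t", {
  for (seed in 1:20) {
    n <- sample(4:28, 1)
    d <- random_2x2(n, seed)
    a <- rm_anova_2x2(d)
    wide_a <- stats::aggregate(value ~ subject_id + coil, d, mean)
    act <- wide_a$value[wide_a$coil == "active"]
    shm <- wide_a$value[wide_a$coil == "sham"]
    t_a <- stats::t.test(act, shm, paired = TRUE)$statistic
    expect_equal(a$F[a$term == "coil"], unname(t_a)^2,
                 tolerance = 1e-8)
    wide_b <- stats::aggregate(value ~ subject_id + score_type, d, mean)
    t_b <- stats::t.test(
      wide_b$value[wide_b$score_type == "FPS"],
      wide_b$value[wide_b$score_type == "APS_ITI"], paired = TRUE)$statistic
    expect_equal(a$F[a$term == "score_type"], unname(t_b)^2,
                 tolerance = 1e-8)
  }
})

test_that("ANOVA matches the aov() within-subject decomposition", {
  d <- random_2x2(9, 101)
  a <- rm_anova_2x2(d)
  fit <- summary(stats::aov(
    value ~ coil * score_type + Error(factor(subject_id) /
                                        (coil * score_type)),
    data = d))
  f_aov <- c(fit[["Error: factor(subject_id):coil"]][[1]]["coil",
                                                          "F value"],
             fit[["Error: factor(subject_id):score_type"]][[1]][
               "score_type", "F value"],
             fit[["Error: factor(subject_id):coil:score_type"]][[1]][
               "coil:score_type", "F value"])
  expect_equal(a$F, unname(f_aov), tolerance = 1e-10)
})

test_that("ANOVA location invariance and degenerate inputs", {
  d <- random_2x2(8, 7)
  shifted <- d
  shifted$value <- shifted$value + 1000
  expect_equal(rm_anova_2x2(d)$F, rm_anova_2x2(shifted)$F,
               tolerance = 1e-6)
  # identical nonzero contrast for every subject: zero error variance
  deg <- expand.grid(subject_id = sprintf("s%d", 1:6),
                     coil = c("active", "sham"),
                     score_type = c("FPS", "APS_ITI"),
                     stringsAsFactors = FALSE)
  deg$value <- as.numeric(factor(deg$subject_id)) +
    2 * (deg$score_type == "FPS")
  expect_error(rm_anova_2x2(deg), "zero error variance")
  expect_error(rm_anova_2x2(random_2x2(2, 1)), "at least 3")
})

test_that("incomplete subjects are removed listwise", {
  d <- random_2x2(8, 15)
  d <- d[!(d$subject_id == "s03" & d$coil == "sham" &
             d$score_type == "FPS"), ]
  expect_message(a <- rm_anova_2x2(d), "s03")
  expect_equal(attr(a, "n_subjects"), 7)
})

test_that("partial eta-squared reproduces the published F pairs", {
  pairs <- rbind(
    c(5.10, 0.16), c(10.48, 0.28), c(46.52, 0.63), c(1.36, 0.05),
    c(1.10, 0.04), c(0.29, 0.01), c(0.07, 0.00), c(0.01, 0.00)
  )
  for (i in seq_len(nrow(pairs))) {
    expect_equal(round(partial_eta_sq(pairs[i, 1], 1, 27), 2),
                 pairs[i, 2])
  }
  expect_equal(partial_eta_sq(0, 1, 27), 0)
  expect_error(partial_eta_sq(-1, 1, 27), "nonnegative")
})

test_that("paired t: hand-computed case, invariances, effect size", {
  # differences (1,2,3): mean 2, sd 1, t = 2*sqrt(3)
  res <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$t, 2 * sqrt(3))
  expect_equal(res$df, 2)
  expect_equal(res$cohens_d, 2)
  # identical vectors have zero difference variance
  expect_error(paired_t(1:4, 1:4), "zero variance")
  # scaling both vectors leaves t unchanged
  set.seed(8)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(paired_t(3 * x, 3 * y)$t, paired_t(x, y)$t)
  expect_error(paired_t(1:3, 1:4), "length")
})

test_that("post-hoc comparisons recover the simple effects", {
  d <- random_2x2(10, 55)
  d$value <- d$value + 2 * (d$coil == "active" & d$score_type == "FPS")
  ph <- posthoc_paired(d)
  expect_equal(nrow(ph), 2)
  fps <- d[d$score_type == "FPS", ]
  ref <- t.test(fps$value[fps$coil == "active"],
                fps$value[fps$coil == "sham"], paired = TRUE)
  expect_equal(abs(ph$t[grepl("FPS", ph$comparison)]),
               abs(unname(ref$statistic)))
})

test_that("required sample size: bound, monotonicity, oracle agreement", {
  n <- required_n(d = 0.6, alpha = 0.025, target_power = 0.8)
  expect_lte(n, 30)
  expect_lt(required_n(d = 0.8), required_n(d = 0.5))
  # continuous-n oracle from power.t.test brackets the integer answer
  ref <- stats::power.t.test(delta = 0.6, sd = 1, sig.level = 0.025,
                             power = 0.8, type = "paired")$n
  expect_equal(n, ceiling(ref))
  expect_error(required_n(d = 0), "positive")
  expect_error(required_n(d = 0.5, alpha = 1.2), "alpha")
})

test_that("returned n is minimal: vectorized Monte-Carlo power check", {
  d <- 0.6; alpha <- 0.025
  n <- required_n(d, alpha, 0.8)
  mc_power <- function(n, reps = 10000) {
    set.seed(123)
    x <- matrix(stats::rnorm(n * reps, mean = d), nrow = n)
    m <- colMeans(x)
    s <- sqrt(colMeans(sweep(x, 2, m)^2) * n / (n - 1))
    tstat <- m / (s / sqrt(n))
    mean(abs(tstat) > stats::qt(1 - alpha / 2, n - 1))
  }
  expect_gte(mc_power(n), 0.8 - 0.013)      # 3 binomial SEs
  expect_lt(mc_power(n - 1), 0.8)
})
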