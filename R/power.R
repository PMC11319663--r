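#' Power of a paired t-test at given n
#'
#' Exact noncentral-t power of the two-sided paired t-test: with effect
#' size `d` (mean difference over SD of differences), the test statistic
#' is noncentral t with `df = n - 1` and noncentrality `d * sqrt(n)`;
#' power is the probability of exceeding the central-t critical value at
#' the stated two-tailed alpha.
#'
#' @param n number of pairs (>= 2).
#' @param d standardized paired effect size.
#' @param alpha two-tailed significance level.
#' @return rejection probability.
#' @export
power_paired_t <- function(n, d, alpha = 0.05) {
  if (n < 2) stop_npu("need n >= 2")
  crit <- stats::qt(1 - alpha / 2, df = n - 1)
  ncp <- d * sqrt(n)
  stats::pt(crit, df = n - 1, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-crit, df = n - 1, ncp = ncp)
}

#' Minimal sample size for a paired t-test
#'
#' Smallest `n` at which the noncentral-t power of the two-sided paired
#' t-test reaches `target_power`. Used for a-priori power analysis, e.g.
#' anticipating a moderate crossover effect (d around 0.5–0.6) at 80%
#' power with a corrected two-tailed alpha of 0.025.
#'
#' @param d standardized effect size (> 0).
#' @param alpha two-tailed significance level.
#' @param target_power desired power in (alpha, 1).
#' @param n_max search cap (error if exceeded).
#' @return minimal integer n.
#' @examples
#' required_n(d = 0.6, alpha = 0.025, target_power = 0.8)
#' @export
required_n <- function(d, alpha = 0.025, target_power = 0.8,
                       n_max = 10000) {
  if (d <= 0) stop_npu("`d` must be positive; power unreachable otherwise")
  if (alpha <= 0 || alpha >= 1) stop_npu("`alpha` must lie in (0, 1)")
  if (target_power <= alpha || target_power >= 1) {
    stop_npu("`target_power` must lie in (alpha, 1)")
  }
  for (n in 2:n_max) {
    if (power_paired_t(n, d, alpha) >= target_power) return(n)
  }
  stop_npu("no n <= ", n_max, " reaches the target power")
}
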