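#' Within-subject 2x2 repeated-measures ANOVA
#'
#' Classical within-subject decomposition for a fully repeated 2x2 design
#' (e.g. coil: active vs sham, by response type: FPS vs APS). Each term's
#' error is its factor-by-subject interaction, giving F with (1, n−1)
#' degrees of freedom; for two-level factors each F equals the squared
#' paired-t statistic on the corresponding per-subject contrast. Partial
#' eta-squared per term is `SS_effect / (SS_effect + SS_error)`,
#' equivalently `F·df1 / (F·df1 + df2)`.
#'
#' Subjects with any missing cell are removed listwise with a message.
#'
#' @param data long data.frame with one value per subject and cell.
#' @param subject,factor_a,factor_b,value column names in `data`.
#' @return An object of class `anova_result`: data.frame with one row per
#'   term (`factor_a`, `factor_b`, interaction): F, df1, df2, p,
#'   partial_eta_sq; attributes `n_subjects` and `factors`.
#' @examples
#' d <- expand.grid(id = 1:6, A = c("a1", "a2"), B = c("b1", "b2"))
#' d$y <- rnorm(nrow(d)) + (d$A == "a2")
#' rm_anova_2x2(d, "id", "A", "B", "y")
#' @export
rm_anova_2x2 <- function(data, subject = "subject_id", factor_a = "coil",
                         factor_b = "score_type", value = "value") {
  for (col in c(subject, factor_a, factor_b, value)) {
    if (!col %in% names(data)) stop_npu("column '", col, "' not found")
  }
  a_lev <- sort(unique(as.character(data[[factor_a]])))
  b_lev <- sort(unique(as.character(data[[factor_b]])))
  if (length(a_lev) != 2L || length(b_lev) != 2L) {
    stop_npu("both factors must have exactly 2 levels")
  }

  # cast to subject x 4-cell matrix; listwise-delete incomplete subjects
  ids <- unique(as.character(data[[subject]]))
  cells <- expand.grid(a = a_lev, b = b_lev, stringsAsFactors = FALSE)
  y <- matrix(NA_real_, nrow = length(ids), ncol = 4L,
              dimnames = list(ids, paste(cells$a, cells$b, sep = ".")))
  for (i in seq_len(nrow(data))) {
    y[as.character(data[[subject]][i]),
      paste(data[[factor_a]][i], data[[factor_b]][i], sep = ".")] <-
      data[[value]][i]
  }
  complete <- stats::complete.cases(y)
  if (any(!complete)) {
    message("rm_anova_2x2: listwise deletion of ",
            sum(!complete), " subject(s) with missing cells: ",
            paste(ids[!complete], collapse = ", "))
  }
  y <- y[complete, , drop = FALSE]
  n <- nrow(y)
  if (n < 3L) stop_npu("need at least 3 complete subjects, got ", n)

  ai <- ifelse(cells$a == a_lev[2], 2L, 1L)   # A level per column
  bi <- ifelse(cells$b == b_lev[2], 2L, 1L)   # B level per column

  gm <- mean(y)
  subj_m <- rowMeans(y)
  m_a <- c(mean(y[, ai == 1L]), mean(y[, ai == 2L]))
  m_b <- c(mean(y[, bi == 1L]), mean(y[, bi == 2L]))
  m_as <- cbind(rowMeans(y[, ai == 1L, drop = FALSE]),
                rowMeans(y[, ai == 2L, drop = FALSE]))
  m_bs <- cbind(rowMeans(y[, bi == 1L, drop = FALSE]),
                rowMeans(y[, bi == 2L, drop = FALSE]))
  cell_m <- colMeans(y)

  ss_a <- 2 * n * sum((m_a - gm)^2)
  ss_b <- 2 * n * sum((m_b - gm)^2)
  ss_axs <- 2 * sum(sweep(sweep(m_as, 2, m_a), 1, subj_m - gm)^2)
  ss_bxs <- 2 * sum(sweep(sweep(m_bs, 2, m_b), 1, subj_m - gm)^2)
  ss_ab <- n * sum((cell_m - m_a[ai] - m_b[bi] + gm)^2)

  # residual (A x B x subject) as the leftover of the full decomposition
  ss_total <- sum((y - gm)^2)
  ss_subj <- 4 * sum((subj_m - gm)^2)
  ss_abxs <- ss_total - ss_subj - ss_a - ss_axs - ss_b - ss_bxs - ss_ab

  df2 <- n - 1L
  terms <- data.frame(
    term = c(factor_a, factor_b,
             paste0(factor_a, ":", factor_b)),
    ss_effect = c(ss_a, ss_b, ss_ab),
    ss_error = c(ss_axs, ss_bxs, ss_abxs),
    stringsAsFactors = FALSE
  )
  tol <- 1e-10 * max(1, ss_total)
  if (any(terms$ss_error <= tol)) {
    bad <- terms$term[terms$ss_error <= tol]
    stop_npu("zero error variance for term(s): ",
             paste(bad, collapse = ", "))
  }
  terms$F <- (terms$ss_effect / 1) / (terms$ss_error / df2)
  terms$df1 <- 1L
  terms$df2 <- df2
  terms$p <- stats::pf(terms$F, 1, df2, lower.tail = FALSE)
  terms$partial_eta_sq <- terms$ss_effect /
    (terms$ss_effect + terms$ss_error)
  out <- terms[, c("term", "F", "df1", "df2", "p", "partial_eta_sq")]
  attr(out, "n_subjects") <- n
  attr(out, "factors") <- c(factor_a, factor_b)
  class(out) <- c("anova_result", class(out))
  out
}

#' Partial eta-squared from an F statistic
#'
#' `F·df1 / (F·df1 + df2)`: the proportion of effect-plus-error variance
#' attributable to the effect. For display, round to 2 decimals — the
#' convention used when reporting ANOVA tables.
#'
#' @param f F statistic (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return value in [0, 1), unrounded.
#' @examples
#' round(partial_eta_sq(5.1, 1, 27), 2)   # 0.16
#' round(partial_eta_sq(46.52, 1, 27), 2) # 0.63
#' @export
partial_eta_sq <- function(f, df1 = 1, df2) {
  if (any(f < 0)) stop_npu("F must be nonnegative")
  if (any(df1 <= 0) || any(df2 <= 0)) stop_npu("dfs must be positive")
  f * df1 / (f * df1 + df2)
}

#' Paired-sample t-test with Cohen's d
#'
#' Two-sided paired t-test (via [stats::t.test()]) plus the within-pair
#' standardized effect `d = mean(diff) / sd(diff)`.
#'
#' @param x,y equal-length paired numeric vectors.
#' @return list: `t`, `df`, `p`, `cohens_d`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop_npu("paired vectors differ in length")
  if (length(x) < 2L) stop_npu("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) stop_npu("zero variance of paired differences")
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = mean(d) / stats::sd(d),
       mean_diff = mean(d))
}

#' Post-hoc paired comparisons for a 2x2 within design
#'
#' Paired t-tests on the simple effects of `factor_a` at each level of
#' `factor_b` (the usual follow-up to a significant main effect or
#' interaction). p-values are reported uncorrected; the companion
#' study-planning convention is a corrected two-tailed alpha of 0.025.
#'
#' @inheritParams rm_anova_2x2
#' @return data.frame: comparison, t, df, p, cohens_d, mean_diff.
#' @export
posthoc_paired <- function(data, subject = "subject_id",
                           factor_a = "coil", factor_b = "score_type",
                           value = "value") {
  a_lev <- sort(unique(as.character(data[[factor_a]])))
  b_lev <- sort(unique(as.character(data[[factor_b]])))
  rows <- lapply(b_lev, function(bl) {
    sub <- data[data[[factor_b]] == bl, ]
    wide <- merge(
      sub[sub[[factor_a]] == a_lev[1], c(subject, value)],
      sub[sub[[factor_a]] == a_lev[2], c(subject, value)],
      by = subject, suffixes = c("_1", "_2")
    )
    res <- paired_t(wide[[paste0(value, "_1")]],
                    wide[[paste0(value, "_2")]])
    data.frame(comparison = paste0(a_lev[1], " vs ", a_lev[2], " @ ",
                                   factor_b, "=", bl),
               t = res$t, df = res$df, p = res$p,
               cohens_d = res$cohens_d, mean_diff = res$mean_diff,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
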