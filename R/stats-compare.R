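# The statistical-test battery used by the analysis: each wrapper
# returns a uniform `test_report` whose `method` field records the exact
# convention used (exact vs approximate, continuity correction, tie
# handling), since those choices move small-sample p-values.

test_report <- function(test, statistic, p_value, method, ...) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(c(list(test = test, statistic = unname(statistic),
                   p_value = min(unname(p_value), 1), method = method),
              list(...)),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat("<test_report>", x$test, " stat =", signif(x$statistic, 4),
      " p =", format.pval(x$p_value, digits = 4), "\n  method:", x$method, "\n")
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null enumeration when `n_x + n_y <= 20` and the data are free
#' of ties (`mode = "auto"`); otherwise the normal approximation with
#' tie correction and continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return A `test_report` with the rank-sum `W` statistic.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("wilcoxon_rank_sum: empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
                  auto = (length(x) + length(y) <= 20) && !ties,
                  exact = TRUE, approx = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE, alternative = "two.sided"))
  test_report("wilcoxon_rank_sum", wt$statistic, wt$p.value,
              if (exact) "exact enumeration of rank splits"
              else "normal approximation, tie-corrected, continuity-corrected",
              n_x = length(x), n_y = length(y))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|`; p-value by exact enumeration when
#' `n_x * n_y <= 400` (and no ties), otherwise the asymptotic Kolmogorov
#' distribution at the effective sample size.
#'
#' @param x,y numeric samples (>= 2 values each).
#' @return A `test_report` with statistic `D`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("ks_two_sample: need >= 2 values per sample")
  exact <- (length(x) * length(y) <= 400) && anyDuplicated(c(x, y)) == 0
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  test_report("ks_two_sample", kt$statistic, kt$p.value,
              if (exact) "exact path enumeration" else "asymptotic Kolmogorov, effective n",
              n_x = length(x), n_y = length(y))
}

#' Pearson chi-squared test on a 2 x k contingency table
#'
#' @param table matrix of non-negative integer counts (2 rows).
#' @param yates apply the Yates continuity correction (2 x 2 only;
#'   default `TRUE` there, ignored otherwise).
#' @return A `test_report`; a warning is attached in `expected_warning`
#'   when any expected count is below 5.
#' @export
chi2_contingency <- function(table, yates = TRUE) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("chi2_contingency: counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi2_contingency: zero margin")
  correct <- yates && all(dim(table) == 2)
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  test_report("chi2_contingency", ct$statistic, ct$p.value,
              paste0("Pearson chi-squared, df=", ct$parameter,
                     if (correct) ", Yates-corrected" else ", uncorrected"),
              df = unname(ct$parameter),
              expected_warning = any(ct$expected < 5))
}

#' Two-proportion z-test (pooled variance, two-sided)
#'
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with the pooled
#' proportion `p`; `z^2` equals the uncorrected 2 x 2 chi-squared.
#'
#' @param s1,n1,s2,n2 successes and totals per group.
#' @return A `test_report` with statistic `z`.
#' @export
two_proportion_ztest <- function(s1, n1, s2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("two_proportion_ztest: group sizes must be > 0")
  if (s1 < 0 || s1 > n1 || s2 < 0 || s2 > n2)
    stop("two_proportion_ztest: successes must lie in [0, n]")
  p1 <- s1 / n1; p2 <- s2 / n2
  p <- (s1 + s2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  test_report("two_proportion_ztest", z, 2 * stats::pnorm(-abs(z)),
              "pooled-variance normal approximation, two-sided",
              p1 = p1, p2 = p2)
}

#' Lilliefors test of composite normality
#'
#' KS distance between the sample ECDF and the Gaussian fitted by the
#' sample mean and s.d. The p-value is computed two ways: the
#' Dallal-Wilkinson analytic approximation (via `nortest`) and a seeded
#' Monte-Carlo null (`n_mc` Gaussian replicates of the same n, refitted
#' each time); the Monte-Carlo value is reported as `p_value`.
#'
#' @param x numeric sample, `n >= 4`, non-constant.
#' @param n_mc Monte-Carlo replicates (default 2000).
#' @param seed integer seed for the null replicates.
#' @return A `test_report` with statistic `D` and extra field
#'   `p_analytic`.
#' @export
lilliefors_normality <- function(x, n_mc = 2000, seed = 1L) {
  if (length(x) < 4) stop("lilliefors_normality: need n >= 4")
  if (stats::sd(x) < 1e-15) stop("lilliefors_normality: constant sample")
  lt <- nortest::lillie.test(x)
  n <- length(x)
  d_null <- withr::with_seed(seed, vapply(seq_len(n_mc), function(i) {
    z <- stats::rnorm(n)
    nortest::lillie.test(z)$statistic
  }, numeric(1)))
  p_mc <- (1 + sum(d_null >= lt$statistic)) / (n_mc + 1)
  test_report("lilliefors_normality", lt$statistic, p_mc,
              sprintf("Monte-Carlo null, %d replicates (analytic Dallal-Wilkinson alongside)", n_mc),
              p_analytic = lt$p.value, n = n)
}

#' Two-sided t-test
#'
#' Welch by default (unequal variances); `pooled = TRUE` gives the
#' classical equal-variance test.
#'
#' @param x,y numeric samples (>= 2 values each).
#' @param pooled use the pooled-variance test.
#' @return A `test_report` with statistic `t` and `df`.
#' @export
t_test_two_sided <- function(x, y, pooled = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("t_test_two_sided: need >= 2 values per sample")
  tt <- stats::t.test(x, y, var.equal = pooled, alternative = "two.sided")
  test_report("t_test_two_sided", tt$statistic, tt$p.value,
              if (pooled) "pooled variance" else "Welch (unequal variances)",
              df = unname(tt$parameter))
}
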