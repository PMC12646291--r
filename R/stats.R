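#' @title Two-group statistical battery
#' @description Descriptives, uncorrected Pearson chi-square with Fisher-exact
#'   and Monte-Carlo fallbacks under the 20% expected-count rule, pooled
#'   t-test, tie-corrected Mann-Whitney U and a Shapiro-Wilk normality gate.
#'   All p-values are two-sided; significance is judged at `alpha` (default
#'   0.05).  No continuity correction is applied to the chi-square statistic
#'   anywhere: the closed form `N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))` for 2x2
#'   tables is the uncorrected one, and it is the convention the published
#'   validation tables follow.
#' @name stats_suite
NULL

new_test_result <- function(test_name, statistic, dof, p_value, alpha = 0.05,
                            note = NULL) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  p_value <- min(p_value, 1)
  structure(list(test_name = test_name, statistic = unname(statistic),
                 dof = dof, p_value = p_value,
                 significant = p_value <= alpha, alpha = alpha, note = note),
            class = "pd_test")
}

#' @export
print.pd_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f%s, p = %.4g%s\n", x$test_name,
              x$statistic,
              if (!is.null(x$dof)) sprintf(", df = %g", x$dof) else "",
              x$p_value, if (x$significant) " *" else ""))
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Descriptive summary of a continuous variable
#'
#' Range, mean, sample standard deviation (n-1 denominator), median and
#' interquartile range.  Quartiles use linear interpolation between order
#' statistics (`stats::quantile()` type 7, the common package default).
#'
#' @param values numeric vector; `NA`s are dropped.
#' @return list with `n, min, max, mean, sd, median, iqr_low, iqr_high`.
#' @export
describe_continuous <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1L)
    stop_pd("describe_continuous: no non-missing values",
            class = "pd_validation_error")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(n = length(values), min = min(values), max = max(values),
       mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else 0,
       median = q[2], iqr_low = q[1], iqr_high = q[3])
}

as_contingency <- function(table) {
  m <- as.matrix(table)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop_pd("contingency table must hold non-negative integer counts",
            class = "pd_validation_error")
  if (sum(m) < 1) stop_pd("contingency table is empty",
                          class = "pd_validation_error")
  storage.mode(m) <- "double"
  m
}

expected_counts <- function(table) {
  m <- as_contingency(table)
  outer(rowSums(m), colSums(m)) / sum(m)
}

#' Pearson chi-square test of independence (no continuity correction)
#'
#' @param table an r x c matrix of observed counts (r, c >= 2, all marginal
#'   totals positive).
#' @param alpha significance level.
#' @return a `pd_test` with the X^2 statistic, `(r-1)(c-1)` degrees of
#'   freedom and the upper-tail chi-square p-value.  Expected counts are
#'   attached as attribute `"expected"`.
#' @examples
#' pearson_chi_square(matrix(c(90, 47, 18, 1), 2))  # X^2 = 6.607
#' @export
pearson_chi_square <- function(table, alpha = 0.05) {
  m <- as_contingency(table)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop_pd("chi-square needs at least a 2x2 table", class = "pd_validation_error")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0))
    stop_pd("empty row (index ", which(rs == 0)[1], ") in contingency table",
            class = "pd_degenerate_error")
  if (any(cs == 0))
    stop_pd("empty column (index ", which(cs == 0)[1], ") in contingency table",
            class = "pd_degenerate_error")
  E <- outer(rs, cs) / sum(m)
  stat <- sum((m - E)^2 / E)
  dof <- (nrow(m) - 1L) * (ncol(m) - 1L)
  res <- new_test_result("chi_square", stat, dof,
                         stats::pchisq(stat, dof, lower.tail = FALSE), alpha)
  attr(res, "expected") <- E
  res
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the probability-mass rule: the hypergeometric probabilities
#' of all tables with the observed margins that are no more probable than the
#' observed table are summed.  The `statistic` field carries the observed
#' table's probability.
#'
#' @param table a 2x2 count matrix.
#' @param alpha significance level.
#' @export
fisher_exact_2x2 <- function(table, alpha = 0.05) {
  m <- as_contingency(table)
  if (!all(dim(m) == c(2L, 2L)))
    stop_pd("fisher_exact_2x2 needs a 2x2 table; use monte_carlo_p for ",
            "larger tables", class = "pd_validation_error")
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); N <- sum(m)
  lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, c1, N - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, N - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  new_test_result("fisher_exact", p_obs, NULL, min(p, 1), alpha)
}

#' Monte-Carlo chi-square p-value under fixed margins
#'
#' Simulates `reps` tables with both margins fixed (Patefield sampling via
#' [stats::r2dtable()]) and estimates the upper-tail p of the observed
#' chi-square statistic with the add-one estimator
#' `(1 + #\{X^2_sim >= X^2_obs\}) / (reps + 1)`, which can never return 0.
#'
#' @param table an r x c count matrix.
#' @param reps number of simulated tables (>= 100).
#' @param seed RNG seed; the caller's RNG state is restored afterwards.
#' @param alpha significance level.
#' @export
monte_carlo_p <- function(table, reps = 10000, seed = NULL, alpha = 0.05) {
  m <- as_contingency(table)
  if (reps < 100) stop_pd("monte_carlo_p: reps must be >= 100",
                          class = "pd_validation_error")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0))
    stop_pd("degenerate margins in contingency table",
            class = "pd_degenerate_error")
  E <- outer(rs, cs) / sum(m)
  stat_obs <- sum((m - E)^2 / E)
  sims <- with_seed(seed, stats::r2dtable(reps, rs, cs))
  stat_sim <- vapply(sims, function(s) sum((s - E)^2 / E), numeric(1))
  p <- (1 + sum(stat_sim >= stat_obs - 1e-12)) / (reps + 1)
  new_test_result("monte_carlo_chi_square", stat_obs,
                  (nrow(m) - 1L) * (ncol(m) - 1L), p, alpha,
                  note = sprintf("%d replicates", reps))
}

#' Categorical test selection under the 20% expected-count rule
#'
#' The asymptotic chi-square test is kept when at most 20% of cells have
#' expected counts below 5; otherwise Fisher's exact test is used for 2x2
#' tables and the Monte-Carlo chi-square for larger ones.
#'
#' @param table an r x c count matrix.
#' @return one of `"chi_square"`, `"fisher_exact"`,
#'   `"monte_carlo_chi_square"`.
#' @export
choose_categorical_test <- function(table) {
  m <- as_contingency(table)
  E <- expected_counts(m)
  if (mean(E < 5) <= 0.2) "chi_square"
  else if (all(dim(m) == c(2L, 2L))) "fisher_exact"
  else "monte_carlo_chi_square"
}

#' Pooled-variance two-sample t-test from group summaries
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 per-group mean, sample SD and size
#'   (`n >= 2`, `sd >= 0`).
#' @param alpha significance level.
#' @return a `pd_test` with the signed t statistic (group 1 minus group 2),
#'   `n1 + n2 - 2` degrees of freedom and the two-sided p.
#' @examples
#' student_t_from_summary(28.61, 4.43, 137, 32.79, 4.52, 19)  # |t| = 3.845
#' @export
student_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                   alpha = 0.05) {
  if (n1 < 2 || n2 < 2)
    stop_pd("student t needs n >= 2 in each group", class = "pd_validation_error")
  if (sd1 < 0 || sd2 < 0) stop_pd("negative SD", class = "pd_validation_error")
  dof <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / dof
  if (sp2 == 0) {
    if (mean1 == mean2)
      return(new_test_result("student_t", 0, dof, 1, alpha,
                             note = "both groups constant and equal"))
    stop_pd("both SDs zero with unequal means: t statistic infinite",
            class = "pd_degenerate_error")
  }
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  new_test_result("student_t", t, dof,
                  2 * stats::pt(abs(t), dof, lower.tail = FALSE), alpha)
}

#' Pooled-variance two-sample t-test from raw values
#'
#' Computes the per-group summaries and delegates to
#' [student_t_from_summary()].
#'
#' @param values1,values2 numeric vectors (each `n >= 2` after `NA` removal).
#' @param alpha significance level.
#' @export
student_t <- function(values1, values2, alpha = 0.05) {
  values1 <- values1[!is.na(values1)]; values2 <- values2[!is.na(values2)]
  student_t_from_summary(mean(values1), stats::sd(values1), length(values1),
                         mean(values2), stats::sd(values2), length(values2),
                         alpha)
}

#' Mann-Whitney U test
#'
#' Midranks handle ties; the reported statistic is `U = min(U1, U2)`.  For
#' tie-free data with `n1 * n2 <= 400` the exact null distribution of U is
#' used; otherwise the normal approximation with tie-corrected variance and a
#' 0.5 continuity correction.
#'
#' @param values1,values2 numeric vectors (each non-empty after `NA`
#'   removal).
#' @param alpha significance level.
#' @export
mann_whitney_u <- function(values1, values2, alpha = 0.05) {
  values1 <- values1[!is.na(values1)]; values2 <- values2[!is.na(values2)]
  n1 <- length(values1); n2 <- length(values2)
  if (n1 < 1L || n2 < 1L)
    stop_pd("mann_whitney_u: both groups must be non-empty",
            class = "pd_validation_error")
  r <- rank(c(values1, values2))
  R1 <- sum(r[seq_len(n1)])
  U1 <- n1 * n2 + n1 * (n1 + 1) / 2 - R1
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  ties <- table(c(values1, values2))
  has_ties <- any(ties > 1)
  if (!has_ties && n1 * n2 <= 400) {
    # exact two-sided p; the U null distribution is symmetric about n1*n2/2
    p <- min(1, 2 * stats::pwilcox(U, n1, n2))
    return(new_test_result("mann_whitney", U, NULL, p, alpha, note = "exact"))
  }
  N <- n1 + n2
  mu <- n1 * n2 / 2
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0)
    return(new_test_result("mann_whitney", U, NULL, 1, alpha,
                           note = "all values tied"))
  z <- (U - mu + 0.5) / sqrt(sigma2)  # U <= mu, correct toward the mean
  p <- min(1, 2 * stats::pnorm(z))
  new_test_result("mann_whitney", U, NULL, p, alpha,
                  note = "normal approximation, tie-corrected")
}

#' Shapiro-Wilk normality gate
#'
#' Routes a continuous variable to the parametric (`"normal"`) or
#' nonparametric (`"non_normal"`) branch of the comparison pipeline.  The W
#' statistic itself is delegated to [stats::shapiro.test()]; a constant
#' vector (for which W is undefined) is surfaced as `"non_normal"`.
#'
#' @param values numeric vector with `3 <= n <= 5000` after `NA` removal.
#' @param alpha gate level.
#' @return `"normal"` or `"non_normal"`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop_pd("normality_gate supports 3 <= n <= 5000 (got ", n, ")",
            class = "pd_validation_error")
  if (diff(range(values)) == 0) return("non_normal")
  p <- stats::shapiro.test(values)$p.value
  if (p < alpha) "non_normal" else "normal"
}
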