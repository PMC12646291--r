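#' Variable plan for the two-group comparison
#'
#' Each plan entry names a cohort variable, its kind and (optionally) how to
#' derive the analysis variable from a raw column.  The default plan mirrors
#' the published validation table: sex, age, BMI, operative time, diabetes,
#' prior recurrence, postoperative infection, midline-pit bins (<5 / 5-10 /
#' >10), lateral pits, hairy back, distance to anus <= 5 cm, prior abscess,
#' and the score itself (requires a `score` column, e.g. from
#' [score_cohort()] — the comparison layer itself never touches a weight
#' table).
#'
#' @param include_score add the `score` row (default `TRUE`).
#' @return list of plan entries (`name`, `field`, `kind`, optional
#'   `transform`).
#' @export
validation_plan <- function(include_score = TRUE) {
  bin_pits <- function(x) factor(ifelse(x < 5, "<5",
                                 ifelse(x <= 10, "5-10", ">10")),
                                 levels = c("<5", "5-10", ">10"))
  near <- function(x) factor(ifelse(x <= 5, "yes", "no"),
                             levels = c("yes", "no"))
  yn <- function(x) factor(ifelse(x, "yes", "no"), levels = c("yes", "no"))
  plan <- list(
    list(name = "sex", field = "sex", kind = "categorical",
         transform = function(x) factor(x, levels = c("male", "female"))),
    list(name = "age", field = "age", kind = "continuous"),
    list(name = "bmi", field = "bmi", kind = "continuous"),
    list(name = "operative_time_min", field = "operative_time_min",
         kind = "continuous"),
    list(name = "diabetes", field = "diabetes", kind = "categorical",
         transform = yn),
    list(name = "prior_recurrence", field = "prior_recurrence",
         kind = "categorical", transform = yn),
    list(name = "postop_infection", field = "postop_infection",
         kind = "categorical", transform = yn),
    list(name = "pit_bins", field = "n_midline_pits", kind = "categorical",
         transform = bin_pits),
    list(name = "lateral_pits", field = "lateral_pits", kind = "categorical",
         transform = yn),
    list(name = "hairy_back", field = "hairy_back", kind = "categorical",
         transform = yn),
    list(name = "distance_anus_le5cm", field = "distance_to_anus_cm",
         kind = "categorical", transform = near),
    list(name = "prior_abscess", field = "prior_abscess",
         kind = "categorical", transform = yn)
  )
  if (include_score)
    plan <- c(plan, list(list(name = "score", field = "score",
                              kind = "continuous")))
  plan
}

#' Two-group comparison report
#'
#' Compares every planned variable between the two levels of a binary
#' outcome.  Categorical variables are cross-tabulated; the reported
#' statistic is always the uncorrected Pearson chi-square, while the p-value
#' comes from the test picked by [choose_categorical_test()] (chi-square,
#' Fisher exact, or Monte-Carlo) — the convention of the published table,
#' which prints the X^2 statistic next to a Fisher/Monte-Carlo p when the
#' expected-count rule fires.  Continuous variables are gated by a pooled
#' Shapiro-Wilk test on within-group mean-centred residuals and sent to the
#' pooled t-test or the Mann-Whitney U accordingly.  Missing values are
#' dropped per variable and counted.
#'
#' No multiplicity correction is applied (none is in the reproduced design);
#' the rendered report footer says so.
#'
#' @param cohort cohort data frame (add a `score` column first if the plan
#'   includes it).
#' @param outcome_field name of the binary outcome column (default
#'   `"recurrence"`).
#' @param plan variable plan, see [validation_plan()].
#' @param alpha significance level (default 0.05).
#' @param mc_reps,mc_seed Monte-Carlo fallback settings.
#' @param verbose log each test-selection decision with `message()`.
#' @return a `comparison_report`: data frame with one row per variable
#'   (`variable, kind, group0, group1, test_name, statistic, dof, p_value,
#'   significant, n_excluded`) plus per-row detail objects in
#'   `attr(, "details")`.
#' @export
compare_groups <- function(cohort, outcome_field = "recurrence",
                           plan = validation_plan(), alpha = 0.05,
                           mc_reps = 10000, mc_seed = 1, verbose = FALSE) {
  if (!outcome_field %in% names(cohort))
    stop_pd("unknown outcome field '", outcome_field, "'",
            class = "pd_validation_error")
  outcome <- as.logical(cohort[[outcome_field]])
  if (any(is.na(outcome)))
    stop_pd("outcome field contains missing values", class = "pd_validation_error")
  n0 <- sum(!outcome); n1 <- sum(outcome)
  if (n0 == 0L || n1 == 0L)
    stop_pd("both outcome groups must be non-empty (got ", n0, " / ", n1, ")",
            class = "pd_degenerate_error")
  say <- function(...) if (verbose) message(...)

  rows <- list(); details <- list()
  for (entry in plan) {
    if (!entry$field %in% names(cohort))
      stop_pd("unknown variable '", entry$field, "' in plan",
              class = "pd_validation_error")
    raw <- cohort[[entry$field]]
    keep <- !is.na(raw)
    n_excl <- sum(!keep)
    x <- raw[keep]; grp <- outcome[keep]
    detail <- list(name = entry$name)

    if (entry$kind == "categorical") {
      v <- if (!is.null(entry$transform)) entry$transform(x) else factor(x)
      tab <- table(v, factor(grp, levels = c(FALSE, TRUE),
                             labels = c("group0", "group1")))
      tab <- unclass(tab)[, , drop = FALSE]
      summ <- function(j) paste(sprintf("%d (%.1f%%)", tab[, j],
                                        100 * tab[, j] / sum(tab[, j])),
                                collapse = " / ")
      if (nlevels(v) < 2L || any(rowSums(tab) == 0)) {
        tr <- new_test_result("degenerate", 0, NULL, 1, alpha,
                              note = "variable constant in cohort")
        warning("variable '", entry$name, "' is degenerate (constant); ",
                "statistic 0 / p 1 reported", call. = FALSE)
        say(entry$name, ": degenerate categorical variable")
      } else {
        chi <- pearson_chi_square(tab, alpha)
        pick <- choose_categorical_test(tab)
        say(entry$name, ": ", pick, " chosen (",
            round(100 * mean(expected_counts(tab) < 5)),
            "% of cells with expected < 5)")
        tr <- switch(pick,
          chi_square = chi,
          fisher_exact = {
            f <- fisher_exact_2x2(tab, alpha)
            new_test_result("fisher_exact", chi$statistic, chi$dof,
                            f$p_value, alpha,
                            note = "statistic is Pearson X^2; p is Fisher exact")
          },
          monte_carlo_chi_square = {
            mc <- monte_carlo_p(tab, reps = mc_reps, seed = mc_seed, alpha = alpha)
            new_test_result("monte_carlo_chi_square", chi$statistic, chi$dof,
                            mc$p_value, alpha,
                            note = "statistic is Pearson X^2; p is Monte-Carlo")
          })
        detail$table <- tab
      }
      g0 <- summ(1); g1 <- summ(2)
    } else {  # continuous
      x <- as.numeric(x)
      s0 <- describe_continuous(x[!grp]); s1 <- describe_continuous(x[grp])
      fmt <- function(s) sprintf("%.2f ± %.2f", s$mean, s$sd)
      g0 <- fmt(s0); g1 <- fmt(s1)
      detail$summary0 <- s0; detail$summary1 <- s1
      if (stats::sd(x) == 0) {
        tr <- new_test_result("degenerate", 0, NULL, 1, alpha,
                              note = "variable constant in cohort")
        warning("variable '", entry$name, "' is degenerate (constant); ",
                "statistic 0 / p 1 reported", call. = FALSE)
      } else {
        resid <- x - ifelse(grp, s1$mean, s0$mean)
        gate <- normality_gate(resid, alpha)
        say(entry$name, ": Shapiro-Wilk on pooled residuals -> ", gate,
            " -> ", if (gate == "normal") "student_t" else "mann_whitney")
        tr <- if (gate == "normal") student_t(x[!grp], x[grp], alpha)
              else mann_whitney_u(x[!grp], x[grp], alpha)
      }
    }
    detail$test <- tr
    rows[[entry$name]] <- data.frame(
      variable = entry$name, kind = entry$kind, group0 = g0, group1 = g1,
      test_name = tr$test_name, statistic = tr$statistic,
      dof = if (is.null(tr$dof)) NA_real_ else tr$dof,
      p_value = tr$p_value, significant = tr$significant,
      n_excluded = n_excl, stringsAsFactors = FALSE)
    details[[entry$name]] <- detail
  }
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  structure(rep, details = details, n_groups = c(group0 = n0, group1 = n1),
            alpha = alpha, outcome_field = outcome_field,
            class = c("comparison_report", "data.frame"))
}

#' @export
print.comparison_report <- function(x, ...) {
  ng <- attr(x, "n_groups")
  cat(sprintf("Two-group comparison by '%s' (n = %d vs %d), alpha = %g\n",
              attr(x, "outcome_field"), ng[1], ng[2], attr(x, "alpha")))
  df <- as.data.frame(x)
  df$statistic <- round(df$statistic, 3)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  cat("No multiple-testing correction applied.\n")
  invisible(x)
}

#' Render a comparison report to TSV or JSON
#'
#' @param report a `comparison_report`.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(report)
  if (format == "tsv") {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines("# No multiple-testing correction applied.", con)
  } else {
    ng <- attr(report, "n_groups")
    jsonlite::write_json(list(
      outcome_field = attr(report, "outcome_field"),
      n_groups = as.list(ng), alpha = attr(report, "alpha"),
      rows = df, footer = "No multiple-testing correction applied."),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
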