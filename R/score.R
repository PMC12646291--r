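#' Validate a patient record
#'
#' Checks one patient record against the domain invariants of the cohort
#' schema: `sex` must be `"male"` or `"female"`; `bmi` and
#' `distance_to_anus_cm` must be positive; `n_midline_pits` must be a
#' non-negative whole number; the boolean factors must be interpretable as
#' logical.  Violations are returned, not thrown, so callers can report all
#' problems in a row at once.
#'
#' @param record a named list or single-row data frame with (at least) the
#'   nine scoring factors.
#' @return a data frame with columns `field` and `message`; zero rows when
#'   the record is valid.
#' @export
validate_record <- function(record) {
  record <- as.list(record)
  v <- list()
  bad <- function(field, message) v[[length(v) + 1L]] <<- data.frame(
    field = field, message = message, stringsAsFactors = FALSE)

  need <- function(field) {
    x <- record[[field]]
    if (is.null(x) || length(x) != 1L || is.na(x)) {
      bad(field, "missing value")
      return(NULL)
    }
    x
  }

  sex <- need("sex")
  if (!is.null(sex) && !as.character(sex) %in% c("male", "female"))
    bad("sex", "must be 'male' or 'female'")

  for (field in c("bmi", "distance_to_anus_cm")) {
    x <- need(field)
    if (!is.null(x) && (!is.numeric(x) || !is.finite(x) || x <= 0))
      bad(field, "must be a positive number")
  }

  pits <- need("n_midline_pits")
  if (!is.null(pits) &&
      (!is.numeric(pits) || !is.finite(pits) || pits < 0 ||
       pits != round(pits)))
    bad("n_midline_pits", "must be a non-negative integer")

  for (field in c("hairy_back", "diabetes", "prior_recurrence",
                  "lateral_pits", "prior_abscess")) {
    x <- need(field)
    if (!is.null(x)) {
      ok <- if (is.numeric(x)) x %in% c(0, 1)
            else !is.na(suppressWarnings(as.logical(x)))
      if (!ok) bad(field, "must be logical (TRUE/FALSE or 0/1)")
    }
  }

  if (!is.null(record$age) && length(record$age) == 1L && !is.na(record$age) &&
      (!is.numeric(record$age) || record$age <= 0))
    bad("age", "must be a positive number of years")

  if (length(v)) do.call(rbind, v)
  else data.frame(field = character(), message = character(),
                  stringsAsFactors = FALSE)
}

#' Compute the Hazem-Talaat score for one patient
#'
#' Sums the nine factor weights for a single patient record.  Outcome fields
#' (recurrence, dehiscence, infection) are never read: the score is strictly
#' preoperative.
#'
#' @param record named list or single-row data frame; must pass
#'   [validate_record()].
#' @param weights a `weight_table`; defaults to the published chart.
#' @return An object of class `score_breakdown`: list with `points` (named
#'   vector of the nine per-factor contributions) and `total`.
#' @examples
#' r <- list(sex = "male", bmi = 34, hairy_back = TRUE, diabetes = TRUE,
#'           prior_recurrence = TRUE, n_midline_pits = 12, lateral_pits = TRUE,
#'           distance_to_anus_cm = 3, prior_abscess = TRUE)
#' compute_score(r)$total  # 27
#' @export
compute_score <- function(record, weights = ht_weights()) {
  validate_weight_table(weights)
  viol <- validate_record(record)
  core <- viol[viol$field %in% c(ht_factor_names, "sex"), , drop = FALSE]
  if (nrow(core))
    stop_pd("invalid record: ",
            paste(core$field, core$message, sep = ": ", collapse = "; "),
            class = "pd_validation_error")
  record <- as.list(record)
  pts <- vapply(names(weights$factors), function(nm) {
    p <- factor_points(weights$factors[[nm]], record[[nm]])
    if (is.na(p))
      stop_pd("weight table does not cover value of factor '", nm, "'",
              class = "pd_config_error")
    as.numeric(p)
  }, numeric(1))
  structure(list(points = pts, total = sum(pts)), class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat("Hazem-Talaat score breakdown\n")
  for (nm in names(x$points))
    cat(sprintf("  %-22s %g\n", nm, x$points[[nm]]))
  cat(sprintf("  total                  %g\n", x$total))
  invisible(x)
}

#' Risk stratification at a score cutoff
#'
#' `"high"` iff `total >= cutoff` (the published rule is high risk at a score
#' of 21 or more), `"low"` otherwise.  Vectorized over `total`.
#'
#' @param total integer score total(s).
#' @param cutoff classification threshold, default 21.
#' @param bounds achievable score bounds (used to sanity-check `cutoff`);
#'   default those of the published chart.
#' @return character vector of `"high"` / `"low"`.
#' @export
classify_risk <- function(total, cutoff = 21, bounds = c(10, 27)) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff))
    stop_pd("cutoff must be a single finite number", class = "pd_validation_error")
  if (cutoff < min(bounds) || cutoff > max(bounds))
    stop_pd("cutoff ", cutoff, " outside achievable score bounds [",
            min(bounds), ", ", max(bounds), "]", class = "pd_validation_error")
  ifelse(total >= cutoff, "high", "low")
}

#' Score a whole cohort
#'
#' Vectorized scoring over a cohort data frame.  Appends one `pts_<factor>`
#' column per factor, the `score` total and the `risk_class` at `cutoff`.
#'
#' @param cohort data frame in the canonical cohort layout (see
#'   [read_cohort()]).
#' @param weights a `weight_table`.
#' @param cutoff risk cutoff passed to [classify_risk()]; `NULL` to skip.
#' @return the cohort with scoring columns appended.
#' @export
score_cohort <- function(cohort, weights = ht_weights(), cutoff = 21) {
  validate_weight_table(weights)
  viol <- validate_cohort(cohort)
  if (nrow(viol))
    stop_pd("invalid cohort: ",
            paste0("row ", viol$row, " ", viol$field, ": ", viol$message,
                   collapse = "; "),
            class = "pd_validation_error")
  out <- cohort
  total <- numeric(nrow(cohort))
  for (nm in names(weights$factors)) {
    p <- factor_points(weights$factors[[nm]], cohort[[nm]])
    out[[paste0("pts_", nm)]] <- p
    total <- total + p
  }
  out$score <- total
  if (!is.null(cutoff))
    out$risk_class <- classify_risk(total, cutoff, score_bounds(weights))
  out
}

#' Validate every row of a cohort
#'
#' @param cohort data frame in the canonical cohort layout.
#' @return data frame with columns `row`, `field`, `message` (zero rows when
#'   all records are valid).
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop_pd("cohort must be a non-empty data frame", class = "pd_validation_error")
  n <- nrow(cohort)
  viol <- list()
  add <- function(rows, field, message) {
    if (length(rows))
      viol[[length(viol) + 1L]] <<- data.frame(row = rows, field = field,
                                               message = message,
                                               stringsAsFactors = FALSE)
  }
  col <- function(field) {
    x <- cohort[[field]]
    if (is.null(x)) {
      add(seq_len(n), field, "missing value")
      return(NULL)
    }
    add(which(is.na(x)), field, "missing value")
    x
  }
  x <- col("sex")
  if (!is.null(x))
    add(which(!is.na(x) & !as.character(x) %in% c("male", "female")), "sex",
        "must be 'male' or 'female'")
  for (field in c("bmi", "distance_to_anus_cm")) {
    x <- col(field)
    if (!is.null(x)) {
      xn <- suppressWarnings(as.numeric(x))
      add(which(!is.na(x) & (is.na(xn) | !is.finite(xn) | xn <= 0)), field,
          "must be a positive number")
    }
  }
  x <- col("n_midline_pits")
  if (!is.null(x)) {
    xn <- suppressWarnings(as.numeric(x))
    add(which(!is.na(x) & (is.na(xn) | !is.finite(xn) | xn < 0 |
                           xn != round(xn))),
        "n_midline_pits", "must be a non-negative integer")
  }
  for (field in c("hairy_back", "diabetes", "prior_recurrence",
                  "lateral_pits", "prior_abscess")) {
    x <- col(field)
    if (!is.null(x)) {
      bad <- if (is.numeric(x)) !is.na(x) & !x %in% c(0, 1)
             else !is.na(x) & is.na(suppressWarnings(as.logical(x)))
      add(which(bad), field, "must be logical (TRUE/FALSE or 0/1)")
    }
  }
  if (!is.null(cohort$age)) {
    a <- cohort$age
    add(which(!is.na(a) & (!is.numeric(a) | a <= 0)), "age",
        "must be a positive number of years")
  }
  if (length(viol)) {
    out <- do.call(rbind, viol)
    out[order(out$row), , drop = FALSE]
  } else data.frame(row = integer(), field = character(),
                    message = character(), stringsAsFactors = FALSE)
}
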