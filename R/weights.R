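#' Weight tables for the Hazem-Talaat score
#'
#' A weight table maps each of the nine scoring factors to a small set of
#' mutually exclusive levels, each carrying a point value.  The default table
#' ([ht_weights()]) is the published Hazem-Talaat chart: BMI (>=30: 2, <30: 1),
#' sex (male 2, female 1), hairy back with hard-textured hair (2/1), diabetes
#' (3/1), previous surgery with recurrence (3/1), number of midline pits
#' (<5: 2, 5-10: 4, >10: 6), lateral pits (3/1), distance of the nearest pit
#' to the anus (>5 cm: 1, <=5 cm: 3) and previous abscess (3/1).
#'
#' Two chart boundaries are undefined in the published table (BMI exactly 30,
#' distance exactly 5 cm).  The default resolves both toward the higher-risk
#' level (BMI 30 counts as obese; 5 cm counts as near), and both are explicit,
#' configurable predicates (`at_boundary`).
#'
#' @section Factor kinds:
#' * `flag` — logical field; points for `yes` / `no`.
#' * `binary` — two-level categorical field; `positive` names the level that
#'   takes the `yes` points.
#' * `threshold` — numeric field split at `threshold`; `at_boundary` says
#'   which side the exact boundary value belongs to (`"above"` or `"below"`).
#' * `bins` — numeric field cut into three ordered bins at `breaks = c(b1,
#'   b2)`: `[0, b1)`, `[b1, b2]`, `(b2, Inf)`.
#'
#' Points must be non-negative finite numbers; the default chart is
#' all-integer but custom tables may use any non-negative reals.
#'
#' @param path for [read_weight_table()], a DCF file (one factor per block;
#'   see `system.file("extdata", "hazem_talaat_weights.dcf", package =
#'   "pdscore")` for the shipped default).
#' @return An object of class `weight_table`.
#' @examples
#' w <- ht_weights()
#' score_bounds(w)  # 10, 27
#' @name weight_table
NULL

ht_factor_names <- c("bmi", "sex", "hairy_back", "diabetes", "prior_recurrence",
                     "n_midline_pits", "lateral_pits", "distance_to_anus_cm",
                     "prior_abscess")

#' @rdname weight_table
#' @export
ht_weights <- function() {
  new_weight_table(list(
    bmi = list(kind = "threshold", threshold = 30, at_boundary = "above",
               points = c(above = 2, below = 1)),
    sex = list(kind = "binary", positive = "male", levels = c("male", "female"),
               points = c(yes = 2, no = 1)),
    hairy_back = list(kind = "flag", points = c(yes = 2, no = 1)),
    diabetes = list(kind = "flag", points = c(yes = 3, no = 1)),
    prior_recurrence = list(kind = "flag", points = c(yes = 3, no = 1)),
    n_midline_pits = list(kind = "bins", breaks = c(5, 10),
                          points = c(low = 2, mid = 4, high = 6)),
    lateral_pits = list(kind = "flag", points = c(yes = 3, no = 1)),
    distance_to_anus_cm = list(kind = "threshold", threshold = 5,
                               at_boundary = "below",
                               points = c(above = 1, below = 3)),
    prior_abscess = list(kind = "flag", points = c(yes = 3, no = 1))
  ), schema_version = "1.0")
}

new_weight_table <- function(factors, schema_version = "1.0") {
  wt <- structure(list(factors = factors, schema_version = schema_version),
                  class = "weight_table")
  validate_weight_table(wt)
  wt
}

#' @rdname weight_table
#' @param wt a `weight_table`.
#' @export
validate_weight_table <- function(wt) {
  if (!inherits(wt, "weight_table"))
    stop_pd("not a weight_table", class = "pd_config_error")
  missing <- setdiff(ht_factor_names, names(wt$factors))
  if (length(missing))
    stop_pd("weight table missing factor(s): ", paste(missing, collapse = ", "),
            class = "pd_config_error")
  for (nm in names(wt$factors)) {
    f <- wt$factors[[nm]]
    pts <- f$points
    if (!is.numeric(pts) || any(!is.finite(pts)) || any(pts < 0))
      stop_pd("factor '", nm, "': points must be finite non-negative numbers",
              class = "pd_config_error")
    n_needed <- switch(f$kind, flag = 2L, binary = 2L, threshold = 2L,
                       bins = 3L,
                       stop_pd("factor '", nm, "': unknown kind '", f$kind, "'",
                               class = "pd_config_error"))
    if (length(pts) != n_needed)
      stop_pd("factor '", nm, "': expected ", n_needed, " point values",
              class = "pd_config_error")
    if (f$kind == "threshold") {
      if (!is.numeric(f$threshold) || !is.finite(f$threshold))
        stop_pd("factor '", nm, "': invalid threshold", class = "pd_config_error")
      if (!f$at_boundary %in% c("above", "below"))
        stop_pd("factor '", nm, "': at_boundary must be 'above' or 'below'",
                class = "pd_config_error")
    }
    if (f$kind == "bins") {
      b <- f$breaks
      if (!is.numeric(b) || length(b) != 2L || any(!is.finite(b)) || b[1] >= b[2])
        stop_pd("factor '", nm, "': breaks must be two increasing numbers",
                class = "pd_config_error")
    }
    if (f$kind == "binary" && (length(f$levels) != 2L ||
                               !f$positive %in% f$levels))
      stop_pd("factor '", nm, "': binary factor needs two levels and a ",
              "'positive' level among them", class = "pd_config_error")
  }
  invisible(wt)
}

# points for one factor given a vector of raw values; NA values propagate
factor_points <- function(f, x) {
  switch(f$kind,
    flag = ifelse(as.logical(x), f$points[["yes"]], f$points[["no"]]),
    binary = ifelse(as.character(x) == f$positive,
                    f$points[["yes"]], f$points[["no"]]),
    threshold = {
      above <- if (f$at_boundary == "above") x >= f$threshold else x > f$threshold
      ifelse(above, f$points[["above"]], f$points[["below"]])
    },
    bins = ifelse(x < f$breaks[1], f$points[[1]],
                  ifelse(x <= f$breaks[2], f$points[[2]], f$points[[3]]))
  )
}

# one representative raw value per level of a factor (used for enumeration)
factor_level_values <- function(f, name) {
  switch(f$kind,
    flag = c(TRUE, FALSE),
    binary = f$levels,
    threshold = {
      eps <- max(1, abs(f$threshold)) * 0.2
      c(f$threshold + eps, f$threshold - eps)
    },
    bins = c(max(0, f$breaks[1] - 1), mean(f$breaks), f$breaks[2] + 1)
  )
}

#' Achievable score bounds of a weight table
#'
#' Minimum and maximum total score achievable under an additive weight table,
#' obtained by summing each factor's smallest / largest point value (valid
#' because the nine factors contribute independently).  The default chart
#' gives 10 and 27.
#'
#' @param wt a `weight_table`.
#' @return named numeric vector `c(min = , max = )`.
#' @export
score_bounds <- function(wt) {
  validate_weight_table(wt)
  lo <- sum(vapply(wt$factors, function(f) min(f$points), numeric(1)))
  hi <- sum(vapply(wt$factors, function(f) max(f$points), numeric(1)))
  c(min = lo, max = hi)
}

#' @rdname weight_table
#' @export
read_weight_table <- function(path) {
  if (!file.exists(path))
    stop_pd("weight table file not found: ", path, class = "pd_io_error")
  blocks <- read.dcf(path, all = TRUE)
  if (!"factor" %in% names(blocks))
    stop_pd("weight table config: every block needs a 'factor' field",
            class = "pd_config_error")
  factors <- list()
  version <- "1.0"
  num <- function(s) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(s), "[[:space:]]+")[[1]]))
    if (any(is.na(v))) stop_pd("weight table config: non-numeric value '", s,
                               "'", class = "pd_config_error")
    v
  }
  for (i in seq_len(nrow(blocks))) {
    row <- lapply(blocks[i, , drop = FALSE], function(x) x[[1]])
    row <- row[!vapply(row, function(x) is.null(x) || is.na(x), logical(1))]
    if (!is.null(row$schema_version) && is.na(row$factor %||% NA)) {
      version <- row$schema_version
      next
    }
    nm <- row$factor
    kind <- row$kind %||% "flag"
    f <- switch(kind,
      flag = list(kind = "flag",
                  points = c(yes = num(row$yes), no = num(row$no))),
      binary = list(kind = "binary", positive = row$positive,
                    levels = strsplit(trimws(row$levels), "[[:space:]]+")[[1]],
                    points = c(yes = num(row$yes), no = num(row$no))),
      threshold = list(kind = "threshold", threshold = num(row$threshold),
                       at_boundary = row$at_boundary %||% "above",
                       points = c(above = num(row$above),
                                  below = num(row$below))),
      bins = list(kind = "bins", breaks = num(row$breaks),
                  points = stats::setNames(num(row$points),
                                           c("low", "mid", "high"))),
      stop_pd("weight table config: unknown kind '", kind, "' for factor '",
              nm, "'", class = "pd_config_error"))
    factors[[nm]] <- f
  }
  new_weight_table(factors[ht_factor_names[ht_factor_names %in% names(factors)]
                           ], schema_version = version)
}

#' @export
print.weight_table <- function(x, ...) {
  cat("Hazem-Talaat weight table (schema ", x$schema_version, ")\n", sep = "")
  b <- score_bounds(x)
  for (nm in names(x$factors)) {
    f <- x$factors[[nm]]
    cat(sprintf("  %-22s %s  points: %s\n", nm, f$kind,
                paste(f$points, collapse = "/")))
  }
  cat(sprintf("  achievable total: %g-%g\n", b[["min"]], b[["max"]]))
  invisible(x)
}

# stable content hash of a weight table (traceability in reports)
weight_table_hash <- function(wt) {
  s <- paste(vapply(names(wt$factors), function(nm) {
    f <- wt$factors[[nm]]
    paste(nm, f$kind, paste(f$points, collapse = ","),
          paste(f$threshold %||% "", f$at_boundary %||% "",
                paste(f$breaks %||% "", collapse = ","), f$positive %||% ""),
          sep = "|")
  }, character(1)), collapse = ";")
  # polynomial rolling hash mod 2^31-1 over the canonical serialization
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
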