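#' Cohort CSV input/output
#'
#' The canonical cohort dialect is a comma-separated UTF-8 file with a
#' mandatory header, booleans serialized as 0/1 and missing values as empty
#' fields.  Columns: `patient_id, sex, age, bmi, hairy_back, diabetes,
#' prior_recurrence, n_midline_pits, lateral_pits, distance_to_anus_cm,
#' prior_abscess, recurrence, wound_dehiscence, postop_infection,
#' operative_time_min, hospital_stay_days, drain_removal_day`.
#'
#' @param path file path.
#' @param cohort data frame in the canonical layout.
#' @return [read_cohort()] returns the cohort data frame with logical boolean
#'   columns; [write_cohort()] returns `path` invisibly.
#' @name cohort_io
NULL

cohort_columns <- c("patient_id", "sex", "age", "bmi", "hairy_back",
                    "diabetes", "prior_recurrence", "n_midline_pits",
                    "lateral_pits", "distance_to_anus_cm", "prior_abscess",
                    "recurrence", "wound_dehiscence", "postop_infection",
                    "operative_time_min", "hospital_stay_days",
                    "drain_removal_day")

cohort_bool_columns <- c("hairy_back", "diabetes", "prior_recurrence",
                         "lateral_pits", "prior_abscess", "recurrence",
                         "wound_dehiscence", "postop_infection")

#' @rdname cohort_io
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop_pd("cohort file not found: ", path, class = "pd_io_error")
  if (file.size(path) == 0L)
    stop_pd("cohort file is empty: ", path, class = "pd_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  missing <- setdiff(c("sex", ht_factor_names), names(df))
  if (length(missing))
    stop_pd("cohort file missing column(s): ", paste(missing, collapse = ", "),
            class = "pd_io_error")
  if (nrow(df) == 0L)
    stop_pd("cohort file has a header but no records: ", path,
            class = "pd_io_error")
  for (col in intersect(cohort_bool_columns, names(df))) {
    x <- df[[col]]
    if (!all(x %in% c(0, 1, NA)))
      stop_pd("column '", col, "' must contain only 0/1 (or empty)",
              class = "pd_io_error")
    df[[col]] <- as.logical(x)
  }
  df
}

#' @rdname cohort_io
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort[, intersect(cohort_columns, names(cohort)), drop = FALSE]
  for (col in intersect(cohort_bool_columns, names(out)))
    out[[col]] <- as.integer(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "",
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
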