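#' Cohort specifications for the stochastic simulators
#'
#' A cohort spec bundles the generative parameters of the two simulation
#' modes.  *Conditional* mode reproduces the case-control structure of the
#' published comparison: the outcome split is fixed (137 / 19), and every
#' covariate is drawn independently given the outcome from its printed
#' group-conditional prevalence (categorical) or mean/SD (continuous).
#' *Prospective* mode is a forward model: covariates are drawn from the
#' printed whole-cohort marginals, the score S is computed, and recurrence
#' follows `Bernoulli(plogis(beta0 + beta1 * S))`.
#'
#' Variables are independent given the outcome (conditional) or mutually
#' independent (prospective): the source tables print only marginals, so no
#' joint dependence is modelled — a documented limitation.
#'
#' [default_cohort_spec()] loads the packaged transcription of the published
#' marginal and group-conditional tables.
#'
#' @param path JSON spec file; defaults to the packaged transcription.
#' @return a `cohort_spec` list.
#' @export
default_cohort_spec <- function(path = system.file("extdata", "cohort_spec.json",
                                           package = "pdscore")) {
  if (!nzchar(path) || !file.exists(path))
    stop_pd("cohort spec file not found: ", path, class = "pd_io_error")
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_cohort_spec(spec)
  spec
}

#' @rdname default_cohort_spec
#' @param spec a cohort spec list.
#' @export
validate_cohort_spec <- function(spec) {
  chk <- function(cond, field, what)
    if (!cond) stop_pd("invalid cohort spec field '", field, "': ", what,
                       class = "pd_config_error")
  chk(is.numeric(spec$n_total) && spec$n_total >= 2, "n_total", "need n >= 2")
  chk(is.numeric(spec$n_recurrent) && spec$n_recurrent >= 1 &&
      spec$n_recurrent < spec$n_total, "n_recurrent",
      "must be in [1, n_total)")
  for (g in c("not_recurrent", "recurrent")) {
    cc <- spec$conditional[[g]]
    chk(is.list(cc), paste0("conditional$", g), "missing block")
    for (f in names(cc$prevalence))
      chk(all(cc$prevalence[[f]] >= 0 & cc$prevalence[[f]] <= 1),
          paste0(g, "$", f), "prevalence outside [0, 1]")
    chk(abs(sum(cc$pit_bin_probs) - 1) < 1e-6, paste0(g, "$pit_bin_probs"),
        "must sum to 1")
    for (f in names(cc$continuous))
      chk(cc$continuous[[f]]$sd >= 0, paste0(g, "$", f), "negative sd")
  }
  m <- spec$marginal
  chk(is.list(m), "marginal", "missing block")
  for (f in names(m$prevalence))
    chk(all(m$prevalence[[f]] >= 0 & m$prevalence[[f]] <= 1),
        paste0("marginal$", f), "prevalence outside [0, 1]")
  chk(abs(sum(m$pit_bin_probs) - 1) < 1e-6, "marginal$pit_bin_probs",
      "must sum to 1")
  invisible(spec)
}

clipnorm <- function(n, mean, sd, lo, hi) pmin(pmax(stats::rnorm(n, mean, sd),
                                                    lo), hi)

draw_pits <- function(n, probs) {
  bin <- sample.int(3L, n, replace = TRUE, prob = probs)
  out <- integer(n)
  out[bin == 1L] <- sample(1:4, sum(bin == 1L), replace = TRUE)
  out[bin == 2L] <- sample(5:10, sum(bin == 2L), replace = TRUE)
  out[bin == 3L] <- sample(11:20, sum(bin == 3L), replace = TRUE)
  out
}

draw_distance <- function(near) {
  out <- numeric(length(near))
  out[near] <- round(stats::runif(sum(near), 1.5, 5), 1)
  out[!near] <- round(stats::runif(sum(!near), 5.1, 12), 1)
  out
}

draw_shared_fields <- function(df, n) {
  df$wound_dehiscence <- stats::runif(n) < 26 / 156
  df$hospital_stay_days <- sample(1:3, n, replace = TRUE,
                                  prob = c(154, 1, 1) / 156)
  df$drain_removal_day <- sample(7:14, n, replace = TRUE,
                                 prob = c(.80, .08, .05, .03, .02, .01,
                                          .005, .005))
  df
}

#' Simulate an outcome-conditional cohort
#'
#' @param spec cohort spec (see [default_cohort_spec()]).
#' @param seed RNG seed (caller's RNG state is restored).
#' @param n cohort size; defaults to `spec$n_total`, keeping the spec's
#'   outcome proportion.
#' @return cohort data frame in the canonical layout.
#' @export
simulate_conditional <- function(spec = default_cohort_spec(), seed = 1,
                                 n = spec$n_total) {
  validate_cohort_spec(spec)
  n_rec <- round(n * spec$n_recurrent / spec$n_total)
  with_seed(seed, {
    rec <- c(rep(FALSE, n - n_rec), rep(TRUE, n_rec))
    df <- data.frame(patient_id = sprintf("S%05d", seq_len(n)),
                     recurrence = rec, stringsAsFactors = FALSE)
    for (part in list(list(sel = !rec, cc = spec$conditional$not_recurrent),
                      list(sel = rec, cc = spec$conditional$recurrent))) {
      k <- sum(part$sel); cc <- part$cc
      prev <- cc$prevalence
      df$sex[part$sel] <- ifelse(stats::runif(k) < prev$male, "male", "female")
      for (f in c("hairy_back", "diabetes", "prior_recurrence",
                  "lateral_pits", "prior_abscess", "postop_infection"))
        df[[f]][part$sel] <- stats::runif(k) < prev[[f]]
      df$n_midline_pits[part$sel] <- draw_pits(k, cc$pit_bin_probs)
      df$distance_to_anus_cm[part$sel] <-
        draw_distance(stats::runif(k) < prev$near_anus)
      for (f in c("age", "bmi", "operative_time_min")) {
        co <- cc$continuous[[f]]
        df[[f]][part$sel] <- clipnorm(k, co$mean, co$sd, co$min, co$max)
      }
    }
    df$age <- as.integer(round(df$age))
    df$bmi <- round(df$bmi, 1)
    df$operative_time_min <- round(df$operative_time_min, 1)
    df <- draw_shared_fields(df, n)
    df[, cohort_columns]
  })
}

#' Simulate a prospective cohort with a logistic outcome model
#'
#' Covariates come from the whole-cohort marginals; recurrence probability
#' is `plogis(beta0 + beta1 * score)`, with the score computed from the
#' supplied weight table.  `beta1 = 0` yields a score with no predictive
#' signal (AUC 0.5); larger slopes give monotonically stronger separation.
#'
#' @param spec cohort spec.
#' @param seed RNG seed.
#' @param n cohort size (default `spec$n_total`).
#' @param beta0,beta1 logistic intercept and slope on the score; defaults
#'   come from the spec (`spec$logistic`).
#' @param weights weight table used to form the score.
#' @return cohort data frame (the realized `score` column is dropped; score
#'   downstream with [score_cohort()]).
#' @export
simulate_prospective <- function(spec = default_cohort_spec(), seed = 1,
                                 n = spec$n_total,
                                 beta0 = spec$logistic$beta0,
                                 beta1 = spec$logistic$beta1,
                                 weights = ht_weights()) {
  validate_cohort_spec(spec)
  if (!is.numeric(beta0) || !is.numeric(beta1))
    stop_pd("prospective mode needs numeric beta0 and beta1",
            class = "pd_config_error")
  m <- spec$marginal
  with_seed(seed, {
    df <- data.frame(patient_id = sprintf("S%05d", seq_len(n)),
                     stringsAsFactors = FALSE)
    prev <- m$prevalence
    df$sex <- ifelse(stats::runif(n) < prev$male, "male", "female")
    for (f in c("hairy_back", "diabetes", "prior_recurrence",
                "lateral_pits", "prior_abscess"))
      df[[f]] <- stats::runif(n) < prev[[f]]
    df$n_midline_pits <- draw_pits(n, m$pit_bin_probs)
    df$distance_to_anus_cm <- draw_distance(stats::runif(n) < prev$near_anus)
    for (f in c("age", "bmi", "operative_time_min")) {
      co <- m$continuous[[f]]
      df[[f]] <- clipnorm(n, co$mean, co$sd, co$min, co$max)
    }
    df$age <- as.integer(round(df$age))
    df$bmi <- round(df$bmi, 1)
    df$operative_time_min <- round(df$operative_time_min, 1)
    score <- score_cohort(df, weights, cutoff = NULL)$score
    df$recurrence <- stats::runif(n) < stats::plogis(beta0 + beta1 * score)
    df$postop_infection <- df$recurrence & (stats::runif(n) < 3 / 19)
    df <- draw_shared_fields(df, n)
    df[, cohort_columns]
  })
}

#' Calibrate the prospective intercept to a target prevalence
#'
#' Solves `mean(plogis(beta0 + beta1 * S)) = target` over a large simulated
#' score sample, giving the `beta0` that makes the prospective simulator hit
#' a requested marginal recurrence rate (e.g. the published 12.2%).
#'
#' @param beta1 logistic slope.
#' @param target target marginal recurrence probability.
#' @param spec cohort spec.
#' @param n score-sample size used for calibration.
#' @param seed RNG seed.
#' @param weights weight table.
#' @return the calibrated `beta0`.
#' @export
calibrate_intercept <- function(beta1, target = 19 / 156, spec = default_cohort_spec(),
                                n = 20000, seed = 1, weights = ht_weights()) {
  stopifnot(target > 0, target < 1)
  df <- simulate_prospective(spec, seed = seed, n = n, beta0 = 0, beta1 = 0,
                             weights = weights)
  s <- score_cohort(df, weights, cutoff = NULL)$score
  f <- function(b0) mean(stats::plogis(b0 + beta1 * s)) - target
  stats::uniroot(f, c(-100, 100), tol = 1e-8)$root
}
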