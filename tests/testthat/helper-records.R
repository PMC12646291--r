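# shared fixtures built in code

make_record <- function(sex = "female", age = 25L, bmi = 24,
                        hairy_back = FALSE, diabetes = FALSE,
                        prior_recurrence = FALSE, n_midline_pits = 3L,
                        lateral_pits = FALSE, distance_to_anus_cm = 7,
                        prior_abscess = FALSE, ...) {
  c(list(sex = sex, age = age, bmi = bmi, hairy_back = hairy_back,
         diabetes = diabetes, prior_recurrence = prior_recurrence,
         n_midline_pits = n_midline_pits, lateral_pits = lateral_pits,
         distance_to_anus_cm = distance_to_anus_cm,
         prior_abscess = prior_abscess), list(...))
}

record_minimal <- function() make_record()  # every factor at its lowest level

record_maximal <- function() make_record(sex = "male", bmi = 34,
                                         hairy_back = TRUE, diabetes = TRUE,
                                         prior_recurrence = TRUE,
                                         n_midline_pits = 12L,
                                         lateral_pits = TRUE,
                                         distance_to_anus_cm = 3,
                                         prior_abscess = TRUE)

# random valid cohort as a data frame (vectorized; for property tests)
random_cohort <- function(n, seed = 1) {
  withr::with_seed(seed, data.frame(
    patient_id = sprintf("R%05d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = sample(18:45, n, replace = TRUE),
    bmi = round(runif(n, 19, 41), 1),
    hairy_back = runif(n) < 0.5, diabetes = runif(n) < 0.5,
    prior_recurrence = runif(n) < 0.5,
    n_midline_pits = sample(0:20, n, replace = TRUE),
    lateral_pits = runif(n) < 0.5,
    distance_to_anus_cm = round(runif(n, 1, 12), 1),
    prior_abscess = runif(n) < 0.5,
    stringsAsFactors = FALSE))
}

# independent oracle: totals of every factor-level combination (3 * 2^8 = 768
# for the default chart), via one compute_score() call per combination
enumerate_totals <- function(weights = ht_weights()) {
  grids <- list(
    bmi = c(25, 35), sex = c("male", "female"),
    hairy_back = c(TRUE, FALSE), diabetes = c(TRUE, FALSE),
    prior_recurrence = c(TRUE, FALSE), n_midline_pits = c(2L, 7L, 12L),
    lateral_pits = c(TRUE, FALSE), distance_to_anus_cm = c(3, 8),
    prior_abscess = c(TRUE, FALSE))
  if (weights$factors$bmi$kind == "threshold") {
    thr <- weights$factors$bmi$threshold
    grids$bmi <- c(thr - 1, thr + 1)
  }
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  vapply(seq_len(nrow(combos)),
         function(i) compute_score(as.list(combos[i, ]), weights)$total,
         numeric(1))
}

# pair-counting Mann-Whitney oracle: wins + half-ties, reported as min(U1,U2)
u_pair_oracle <- function(v1, v2) {
  wins <- sum(outer(v1, v2, ">")) + 0.5 * sum(outer(v1, v2, "=="))
  min(wins, length(v1) * length(v2) - wins)
}

# concordance AUC oracle: P(score_pos > score_neg) + P(tie)/2 by brute force
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# hypergeometric enumeration oracle for a 2x2 Fisher test, written with
# explicit binomial-coefficient arithmetic (independent of dhyper)
fisher_enum_oracle <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); N <- sum(m)
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(N, c1)
  p <- exp(logp)
  p_obs <- p[support == m[1, 1]]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# the nine published categorical tables (columns: not recurrent, recurrent)
published_tables <- function() list(
  sex = matrix(c(90, 47, 18, 1), 2),
  diabetes = matrix(c(11, 126, 10, 9), 2),
  prior_recurrence = matrix(c(15, 122, 11, 8), 2),
  postop_infection = matrix(c(0, 137, 3, 16), 2),
  pit_bins = matrix(c(79, 47, 11, 4, 3, 12), 3),
  lateral_pits = matrix(c(27, 110, 15, 4), 2),
  hairy_back = matrix(c(48, 89, 16, 3), 2),
  distance_anus_le5cm = matrix(c(23, 114, 15, 4), 2),
  prior_abscess = matrix(c(35, 102, 14, 5), 2))

published_chisq <- c(sex = 6.607, diabetes = 28.495, prior_recurrence = 26.477,
                  postop_infection = 22.056, pit_bins = 40.384,
                  lateral_pits = 29.762, hairy_back = 16.676,
                  distance_anus_le5cm = 34.990, prior_abscess = 17.946)

# group-conditional cell counts of a cohort, in the published layout
fixture_cells <- function(cohort) {
  g <- function(x) c(sum(x[!cohort$recurrence]), sum(x[cohort$recurrence]))
  list(male = g(cohort$sex == "male"), diabetes = g(cohort$diabetes),
       prior_recurrence = g(cohort$prior_recurrence),
       postop_infection = g(cohort$postop_infection),
       pits_lt5 = g(cohort$n_midline_pits < 5),
       pits_5to10 = g(cohort$n_midline_pits >= 5 & cohort$n_midline_pits <= 10),
       pits_gt10 = g(cohort$n_midline_pits > 10),
       lateral_pits = g(cohort$lateral_pits), hairy_back = g(cohort$hairy_back),
       near_anus = g(cohort$distance_to_anus_cm <= 5),
       prior_abscess = g(cohort$prior_abscess))
}

published_cells <- list(
  male = c(90, 18), diabetes = c(11, 10), prior_recurrence = c(15, 11),
  postop_infection = c(0, 3), pits_lt5 = c(79, 4), pits_5to10 = c(47, 3),
  pits_gt10 = c(11, 12), lateral_pits = c(27, 15), hairy_back = c(48, 16),
  near_anus = c(23, 15), prior_abscess = c(35, 14))
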