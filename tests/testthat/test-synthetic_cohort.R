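test_that("the reconstruction fixture matches every published cell exactly", {
  fx <- reconstruct_fixture()
  expect_equal(nrow(fx), 156)
  expect_equal(sum(fx$recurrence), 19)
  expect_equal(fixture_cells(fx), published_cells)
  expect_equal(nrow(validate_cohort(fx)), 0)
  # whole-cohort marginals follow from the cells
  expect_equal(sum(fx$sex == "male"), 108)
  expect_equal(sum(fx$wound_dehiscence), 26)
  expect_equal(as.integer(table(fx$hospital_stay_days)), c(154L, 1L, 1L))
})

test_that("the fixture yields the published confusion matrix and cutoff", {
  scored <- score_cohort(reconstruct_fixture())
  expect_true(all(scored$score >= 10 & scored$score <= 27))
  cm <- confusion_at(scored$score, scored$recurrence, 21)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(12, 2, 7, 135))
  cv <- roc_curve(scored$score, scored$recurrence)
  expect_equal(youden_cutoff(cv)$cutoff, 21)
  expect_gte(auc(cv)$auc, 0.9)
  # BMI indicator consistent with the continuous assignment
  expect_equal(scored$pts_bmi == 2, scored$bmi >= 30)
  # best-effort continuous targets: group means within 0.5 of the printed ones
  expect_lt(abs(mean(scored$bmi[!scored$recurrence]) - 28.61), 0.5)
  expect_lt(abs(mean(scored$bmi[scored$recurrence]) - 32.79), 0.5)
  expect_lt(abs(mean(scored$age[!scored$recurrence]) - 27.29), 0.5)
  expect_lt(abs(mean(scored$score[scored$recurrence]) - 22.11), 0.5)
  expect_lt(abs(mean(scored$score[!scored$recurrence]) - 13.96), 0.5)
  # whole-cohort BMI moments land near the published 29.12 +/- 4.63
  d <- describe_continuous(scored$bmi)
  expect_lt(abs(d$mean - 29.12), 0.5)
  expect_lt(abs(d$sd - 4.63), 0.5)
})

test_that("the fixture is deterministic and byte-stable", {
  expect_identical(reconstruct_fixture(), reconstruct_fixture())
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(reconstruct_fixture(), f1)
  write_cohort(reconstruct_fixture(), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("conditional simulator recovers its prevalences at n = 10000", {
  spec <- default_cohort_spec()
  cohort <- simulate_conditional(spec, seed = 2024, n = 10000)
  expect_equal(nrow(validate_cohort(cohort)), 0)
  for (g in c("not_recurrent", "recurrent")) {
    sel <- if (g == "recurrent") cohort$recurrence else !cohort$recurrence
    k <- sum(sel)
    prev <- spec$conditional[[g]]$prevalence
    obs <- c(male = mean(cohort$sex[sel] == "male"),
             hairy_back = mean(cohort$hairy_back[sel]),
             diabetes = mean(cohort$diabetes[sel]),
             prior_recurrence = mean(cohort$prior_recurrence[sel]),
             lateral_pits = mean(cohort$lateral_pits[sel]),
             prior_abscess = mean(cohort$prior_abscess[sel]),
             near_anus = mean(cohort$distance_to_anus_cm[sel] <= 5))
    for (nm in names(obs)) {
      p <- prev[[nm]]
      expect_lt(abs(obs[[nm]] - p), 4 * sqrt(p * (1 - p) / k) + 1e-9,
                label = paste(g, nm, "prevalence deviation"))
    }
    bins <- spec$conditional[[g]]$pit_bin_probs
    obs_bins <- c(mean(cohort$n_midline_pits[sel] < 5),
                  mean(cohort$n_midline_pits[sel] >= 5 &
                       cohort$n_midline_pits[sel] <= 10),
                  mean(cohort$n_midline_pits[sel] > 10))
    for (j in 1:3)
      expect_lt(abs(obs_bins[j] - bins[j]),
                4 * sqrt(bins[j] * (1 - bins[j]) / k))
  }
  # continuous moments (clipping perturbs them only slightly)
  rec <- cohort$recurrence
  expect_lt(abs(mean(cohort$bmi[rec]) - 32.79), 0.5)
  expect_lt(abs(mean(cohort$bmi[!rec]) - 28.61), 0.5)
  expect_lt(abs(sd(cohort$bmi[!rec]) - 4.43), 0.5)
})

test_that("conditional simulator is seed-reproducible and honours edge specs", {
  expect_identical(simulate_conditional(seed = 5, n = 400),
                   simulate_conditional(seed = 5, n = 400))
  spec <- default_cohort_spec()
  for (g in c("not_recurrent", "recurrent"))
    spec$conditional[[g]]$prevalence <- lapply(
      spec$conditional[[g]]$prevalence, function(x) 0)
  cohort <- simulate_conditional(spec, seed = 1, n = 300)
  expect_true(all(cohort$sex == "female"))
  expect_true(!any(cohort$diabetes | cohort$lateral_pits |
                   cohort$prior_abscess))
  spec$n_recurrent <- -1
  expect_error(validate_cohort_spec(spec), class = "pd_config_error")
})

test_that("prospective simulator: no signal at zero slope, monotone in the slope", {
  spec <- default_cohort_spec()
  d0 <- simulate_prospective(spec, seed = 11, n = 5000, beta0 = 0, beta1 = 0)
  s0 <- score_cohort(d0)
  expect_lt(abs(auc(s0$score, s0$recurrence)$auc - 0.5), 0.03)
  slopes <- c(0, 0.2, 0.5, 1, 2)
  aucs <- vapply(slopes, function(b1) {
    d <- simulate_prospective(spec, seed = 11, n = 5000,
                              beta0 = -15 * b1, beta1 = b1)
    s <- score_cohort(d)
    auc(s$score, s$recurrence)$auc
  }, numeric(1))
  expect_true(all(diff(aucs) > -0.01))
  expect_gt(aucs[length(aucs)], 0.95)
})

test_that("packaged logistic parameters hit the published recurrence rate", {
  spec <- default_cohort_spec()
  d <- simulate_prospective(spec, seed = 1, n = 10000)
  p <- 19 / 156
  expect_lt(abs(mean(d$recurrence) - p), 4 * sqrt(p * (1 - p) / 10000))
})
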