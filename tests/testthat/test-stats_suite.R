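test_that("describe_continuous computes the documented summaries", {
  d <- describe_continuous(c(1, 2, 3, 4, 5))
  expect_equal(d$mean, 3)
  expect_equal(d$sd, sqrt(2.5), tolerance = 1e-12)
  expect_equal(d$median, 3)
  expect_equal(c(d$iqr_low, d$iqr_high), c(2, 4))
  d <- describe_continuous(rep(7, 100))
  expect_equal(c(d$mean, d$sd), c(7, 0))
  expect_error(describe_continuous(numeric(0)), class = "pd_validation_error")
})

test_that("pearson chi-square equals the 2x2 closed form and the printed values", {
  withr::with_seed(11, for (i in 1:25) {
    m <- matrix(rpois(4, 20) + 1, 2)
    a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]; N <- sum(m)
    closed <- N * (a * d - b * cc)^2 /
      ((a + b) * (cc + d) * (a + cc) * (b + d))
    res <- pearson_chi_square(m)
    expect_equal(res$statistic, closed, tolerance = 1e-9)
    expect_equal(res$dof, 1)
    expect_equal(res$p_value, pchisq(closed, 1, lower.tail = FALSE))
  })
  for (nm in names(published_tables()))
    expect_equal(round(pearson_chi_square(published_tables()[[nm]])$statistic, 3),
                 unname(published_chisq[nm]), info = nm)
  expect_equal(pearson_chi_square(matrix(10, 2, 2))$statistic, 0)
  expect_error(pearson_chi_square(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "row", class = "pd_degenerate_error")
})

test_that("fisher_exact_2x2 equals hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2))$p_value, 1)
  m <- matrix(c(0, 137, 3, 16), 2)  # postoperative infection table
  p <- fisher_exact_2x2(m)$p_value
  expect_lt(p, 0.05)
  expect_equal(p, fisher_enum_oracle(m), tolerance = 1e-12)
  expect_equal(p, fisher.test(m)$p.value, tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(matrix(c(2, 8, 7, 2), 2))$p_value,
               fisher_enum_oracle(matrix(c(2, 8, 7, 2), 2)), tolerance = 1e-12)
  withr::with_seed(5, for (i in 1:40) {
    m <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact_2x2(m)$p_value, fisher_enum_oracle(m),
                 tolerance = 1e-12, info = paste(m, collapse = ","))
  })
  expect_error(fisher_exact_2x2(matrix(1, 3, 2)), "monte_carlo",
               class = "pd_validation_error")
})

test_that("monte_carlo_p is seeded, calibrated and matches the asymptotic tail", {
  m <- matrix(10, 2, 2)
  expect_equal(monte_carlo_p(m, reps = 1000, seed = 1)$p_value, 1,
               tolerance = 2 / 1001)
  p <- monte_carlo_p(matrix(c(79, 47, 11, 4, 3, 12), 3), reps = 10000,
                     seed = 1)$p_value
  expect_lt(p, 0.001)
  expect_identical(monte_carlo_p(m, reps = 500, seed = 9)$p_value,
                   monte_carlo_p(m, reps = 500, seed = 9)$p_value)
  # agreement with the chi-square tail on a well-populated table, 20 seeds
  # (all E >= 10; a multi-df table, where the conditional null has fine
  # enough support for the asymptotic tail to be the right reference)
  m <- matrix(c(60, 45, 50, 40, 42, 55), 2)
  asym <- pearson_chi_square(m)$p_value
  reps <- 4000
  for (seed in 1:20) {
    mc <- monte_carlo_p(m, reps = reps, seed = seed)$p_value
    expect_lt(abs(mc - asym), 3 * sqrt(asym * (1 - asym) / reps))
  }
  # for a 2x2 the conditional null is exactly enumerable: stronger oracle
  m2 <- matrix(c(40, 25, 30, 35), 2)
  r1 <- sum(m2[1, ]); c1 <- sum(m2[, 1]); N <- sum(m2)
  supp <- max(0, r1 + c1 - N):min(r1, c1)
  chi_at <- vapply(supp, function(k)
    pearson_chi_square(matrix(c(k, c1 - k, r1 - k, N - r1 - c1 + k), 2)
                       )$statistic, numeric(1))
  exact_tail <- sum(dhyper(supp, c1, N - c1, r1)[
    chi_at >= pearson_chi_square(m2)$statistic - 1e-12])
  for (seed in 1:5) {
    mc <- monte_carlo_p(m2, reps = reps, seed = seed)$p_value
    expect_lt(abs(mc - exact_tail),
              3 * sqrt(exact_tail * (1 - exact_tail) / reps))
  }
  expect_error(monte_carlo_p(m, reps = 50, seed = 1),
               class = "pd_validation_error")
})

test_that("the 20% expected-count rule picks the documented tests", {
  expect_equal(choose_categorical_test(matrix(c(90, 47, 18, 1), 2)),
               "chi_square")  # all E >= 5 (smallest 48*19/156 = 5.85)
  expect_equal(choose_categorical_test(matrix(c(0, 137, 3, 16), 2)),
               "fisher_exact")
  # pit-bin table: only 1 of 6 cells has E < 5 (16.7%), so chi-square stays —
  # consistent with the published row carrying no Fisher/Monte-Carlo flag
  expect_equal(choose_categorical_test(matrix(c(79, 47, 11, 4, 3, 12), 3)),
               "chi_square")
  expect_equal(choose_categorical_test(matrix(c(6, 5, 4, 2, 1, 3), 3)),
               "monte_carlo_chi_square")
  expect_equal(choose_categorical_test(matrix(c(30, 45, 25, 40, 22, 38), 2)),
               "chi_square")
})

test_that("pooled t reproduces printed statistics and closed-form arithmetic", {
  t_bmi <- student_t_from_summary(28.61, 4.43, 137, 32.79, 4.52, 19)
  expect_equal(abs(t_bmi$statistic), 3.844, tolerance = 0.005 / 3.844)
  expect_equal(t_bmi$dof, 154)
  expect_true(t_bmi$significant)
  t_age <- student_t_from_summary(27.29, 6.44, 137, 27.47, 6.88, 19)
  expect_equal(abs(t_age$statistic), 0.114, tolerance = 0.005 / 0.114)
  expect_false(t_age$significant)
  expect_equal(student_t_from_summary(5, 1, 10, 5, 2, 12)$statistic, 0)
  # hand arithmetic: sp2 = 1/3, t = -10 / sqrt((1/3)(1/2)) = -sqrt(600)
  expect_equal(student_t(c(0, 0, 1, 1), c(10, 10, 11, 11))$statistic,
               -sqrt(600), tolerance = 1e-12)
  r <- student_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(r$statistic, r$p_value), c(0, 1))
  expect_equal(student_t_from_summary(3, 0, 5, 3, 0, 5)$p_value, 1)
  expect_error(student_t_from_summary(3, 0, 5, 4, 0, 5),
               class = "pd_degenerate_error")
  # matches the standard implementation on random draws
  withr::with_seed(21, for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(12, 0.5)
    ref <- t.test(x, y, var.equal = TRUE)
    mine <- student_t(x, y)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  })
})

test_that("pooled t holds its nominal type-I error under the null", {
  hits <- withr::with_seed(99, vapply(1:1000, function(i)
    student_t(rnorm(50), rnorm(50))$p_value <= 0.05, logical(1)))
  expect_gte(mean(hits), 0.03)
  expect_lte(mean(hits), 0.07)
})

test_that("mann_whitney_u equals the pair-counting oracle, ties included", {
  expect_equal(mann_whitney_u(1:10, 1:10)$statistic, 50)
  expect_equal(mann_whitney_u(1:3, 4:6)$statistic, 0)
  withr::with_seed(31, for (i in 1:40) {
    n1 <- sample(2:50, 1); n2 <- sample(2:50, 1)
    v1 <- sample(1:12, n1, replace = TRUE)   # heavy ties
    v2 <- sample(1:12, n2, replace = TRUE)
    expect_equal(mann_whitney_u(v1, v2)$statistic, u_pair_oracle(v1, v2))
    w1 <- rnorm(n1); w2 <- rnorm(n2)         # tie-free
    expect_equal(mann_whitney_u(w1, w2)$statistic, u_pair_oracle(w1, w2))
  })
  # exact branch agrees with the reference distribution
  withr::with_seed(32, for (i in 1:10) {
    v1 <- rnorm(8); v2 <- rnorm(9, 0.8)
    ref <- wilcox.test(v1, v2, exact = TRUE, correct = FALSE)
    expect_equal(mann_whitney_u(v1, v2)$p_value, ref$p.value,
                 tolerance = 1e-12)
  })
  expect_error(mann_whitney_u(numeric(0), 1:3), class = "pd_validation_error")
})

test_that("the Shapiro-Wilk gate routes distributions as documented", {
  normal_hits <- vapply(1:100, function(s) withr::with_seed(s,
    normality_gate(rnorm(500)) == "normal"), logical(1))
  expect_gte(mean(normal_hits), 0.9)
  expon_hits <- vapply(1:100, function(s) withr::with_seed(s,
    normality_gate(rexp(500)) == "non_normal"), logical(1))
  expect_gte(mean(expon_hits), 0.9)
  expect_equal(normality_gate(rep(3, 10)), "non_normal")
  expect_error(normality_gate(c(1, 2)), class = "pd_validation_error")
})

test_that("compare_groups reproduces the full categorical panel on the fixture", {
  scored <- score_cohort(reconstruct_fixture())
  rep <- compare_groups(scored, verbose = FALSE)
  for (nm in names(published_chisq)) {
    row <- rep[rep$variable == nm, ]
    expect_equal(round(row$statistic, 3), unname(published_chisq[nm]), info = nm)
  }
  # selection rule: infection/diabetes/prior-recurrence/distance rows carry
  # Fisher p-values; sex and the rest stay asymptotic
  expect_equal(rep$test_name[rep$variable == "postop_infection"],
               "fisher_exact")
  expect_equal(rep$test_name[rep$variable == "sex"], "chi_square")
  expect_equal(rep$test_name[rep$variable == "pit_bins"], "chi_square")
  expect_true(all(rep$significant[rep$variable != "age"]))
  expect_false(rep$significant[rep$variable == "age"])
  expect_true(all(rep$n_excluded == 0))
})

test_that("compare_groups flags degenerate variables and missing data", {
  scored <- score_cohort(reconstruct_fixture())
  scored$diabetes <- FALSE
  expect_warning(rep <- compare_groups(scored, verbose = FALSE), "degenerate")
  row <- rep[rep$variable == "diabetes", ]
  expect_equal(c(row$statistic, row$p_value), c(0, 1))
  scored$age[1:5] <- NA
  rep <- suppressWarnings(compare_groups(scored, verbose = FALSE))
  expect_equal(rep$n_excluded[rep$variable == "age"], 5)
  scored$recurrence <- FALSE
  expect_error(suppressWarnings(compare_groups(scored)),
               class = "pd_degenerate_error")
})

test_that("compare_groups holds ~5% false-positive row rate on null cohorts", {
  # same generative distribution in both groups: copy the non-recurrent block
  spec <- default_cohort_spec()
  spec$conditional$recurrent <- spec$conditional$not_recurrent
  spec$conditional$recurrent$prevalence$postop_infection <- 0.05
  spec$conditional$not_recurrent$prevalence$postop_infection <- 0.05
  flags <- unlist(lapply(1:200, function(s) {
    cohort <- simulate_conditional(spec, seed = s)
    scored <- score_cohort(cohort)
    rep <- suppressWarnings(compare_groups(scored, mc_reps = 2000,
                                           mc_seed = s, verbose = FALSE))
    rep$significant
  }))
  expect_gte(mean(flags), 0.03)
  expect_lte(mean(flags), 0.07)
})
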