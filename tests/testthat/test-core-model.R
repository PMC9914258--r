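test_that("odds-ratio inversion gives the genuine-case prevalence", {
  expect_equal(invert_odds_ratio(1, 0.25), 0.25)
  expect_equal(invert_odds_ratio(3, 0.25), 0.5)
  expect_equal(invert_odds_ratio(10, 0.05), 10 / 29)
  # boundaries carry through for any odds ratio
  expect_equal(invert_odds_ratio(7, 0), 0)
  expect_equal(invert_odds_ratio(7, 1), 1)
  expect_error(invert_odds_ratio(0, 0.25), "delta_t")
  expect_error(invert_odds_ratio(-2, 0.25), "delta_t")
  expect_error(invert_odds_ratio(Inf, 0.25), "delta_t")
})

test_that("inversion round-trips through the odds ratio", {
  set.seed(101)
  for (i in 1:200) {
    theta0 <- runif(1, 0.01, 0.99)
    delta <- exp(runif(1, log(0.1), log(20)))
    t1s <- invert_odds_ratio(delta, theta0)
    or_back <- (t1s / (1 - t1s)) / (theta0 / (1 - theta0))
    expect_equal(or_back, delta, tolerance = 1e-12)
  }
})

test_that("case exposure probability is the mixture of the two strata", {
  expect_equal(case_exposure_prob(0, 0.25, 0.5), 0.5)
  expect_equal(case_exposure_prob(1, 0.25, 0.5), 0.25)
  expect_equal(case_exposure_prob(0.5, 0.25, 0.5), 0.375)
  expect_error(case_exposure_prob(1.2, 0.25, 0.5), "gamma")
  # linear, monotone decreasing in gamma when genuine cases are enriched
  g <- seq(0, 1, 0.1)
  v <- case_exposure_prob(g, 0.25, 0.5)
  expect_true(all(diff(v) < 0))
  expect_equal(diff(v), rep(diff(v)[1], 10))  # linearity
  expect_true(all(v >= 0.25 & v <= 0.5))
  expect_equal(case_exposure_prob(g, 0.3, 0.3), rep(0.3, 11))
})

test_that("serology formula mixes true and false positives", {
  expect_equal(case_exposure_prob_serology(0, 0.25, 0.5, 0.975, 0.975), 0.5)
  expect_equal(case_exposure_prob_serology(1, 0.25, 0.5, 0.9, 0.9), 0.3)
  expect_error(case_exposure_prob_serology(0.5, 0.25, 0.5, 1.5, 1), "pi_se")
})

test_that("serology formula reduces to the perfect-test mixture", {
  set.seed(202)
  for (i in 1:1000) {
    g <- runif(1); t0 <- runif(1); t1s <- runif(1)
    expect_equal(case_exposure_prob_serology(g, t0, t1s, 1, 1),
                 case_exposure_prob(g, t0, t1s), tolerance = 1e-15)
  }
})

test_that("control observed-positive probability handles imperfect tests", {
  expect_equal(control_observed_prob(0.25, 1, 1), 0.25)
  expect_equal(control_observed_prob(0.25, 0.9, 0.9), 0.3)
  expect_equal(control_observed_prob(0, 0.8, 0.8), 0.2)
})

test_that("Pearson chi-squared matches hand-computed values", {
  res <- pearson_chi2(table2x2(10, 20, 20, 10))
  expect_equal(res$statistic, 4 * 25 / 15)  # all expected counts are 15
  expect_equal(res$p_value, 0.00982, tolerance = 1e-3)
  expect_false(res$degenerate)

  flat <- pearson_chi2(table2x2(15, 15, 15, 15))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  degen <- pearson_chi2(table2x2(0, 20, 0, 10))  # empty "present" row
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)
  expect_error(pearson_chi2(table2x2(0, 0, 0, 0)), "observations")
})

test_that("chi-squared agrees with the textbook oracle and chisq.test", {
  for (m in random_tables(1000, seed = 7)) {
    mine <- pearson_chi2(m)
    expect_equal(mine$statistic, oracle_chi2(m), tolerance = 1e-10)
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    yat <- pearson_chi2(m, yates = TRUE)
    refy <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
    expect_equal(yat$statistic, unname(refy$statistic), tolerance = 1e-10)
  }
})

test_that("scenario construction validates and derives consistently", {
  p <- scenario_params(theta0 = 0.25, delta_t = 3, n0 = 100)
  expect_equal(p$theta1_star, 0.5)
  expect_equal(p$n1, 100L)  # defaults to n0
  or_back <- (p$theta1_star / (1 - p$theta1_star)) /
    (p$theta0 / (1 - p$theta0))
  expect_equal(or_back, 3, tolerance = 1e-12)

  expect_error(scenario_params(theta0 = 0.25, delta_t = 3,
                               theta1_star = 0.5, n0 = 100),
               "exactly one")
  expect_error(scenario_params(theta0 = 0.25, n0 = 100), "exactly one")
  expect_error(scenario_params(theta0 = 1.2, delta_t = 3, n0 = 100),
               "theta0")
  expect_error(scenario_params(theta0 = 0.25, delta_t = 3, n0 = 0), "n0")
  expect_error(scenario_params(theta0 = 0.25, delta_t = 3, n0 = 100,
                               alpha = 1), "alpha")
  # odds ratio undefined at the prevalence boundary: pinned with warning
  expect_warning(pb <- scenario_params(theta0 = 0, delta_t = 3, n0 = 50),
                 "boundary")
  expect_equal(pb$theta1_star, 0)
})
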