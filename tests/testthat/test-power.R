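test_that("full misdiagnosis calibrates the power to the test level", {
  p <- scenario_params(theta0 = 0.25, delta_t = 3, gamma = 1, n0 = 500)
  est <- estimate_power(p, replicates = 4000, seed = 1)
  expect_lt(abs(est$power - 0.05), 4 * sqrt(0.05 * 0.95 / 4000))
})

test_that("a null effect keeps the rejection rate at the test level", {
  p <- scenario_params(theta0 = 0.25, delta_t = 1, gamma = 0.3, n0 = 250)
  est <- estimate_power(p, replicates = 4000, seed = 2)
  expect_lt(abs(est$power - 0.05), 4 * sqrt(0.05 * 0.95 / 4000))
})

test_that("power curves fall from a genuine cohort to a fully apparent one", {
  p <- scenario_params(theta0 = 0.1, delta_t = 10, n0 = 250)
  pc <- power_curve(p, gamma_grid = c(0, 1), replicates = 2000, seed = 3)
  expect_equal(nrow(pc$data), 2)
  expect_gt(pc$data$power[1], pc$data$power[2])
  expect_lt(abs(pc$data$power[2] - 0.05), 4 * sqrt(0.05 * 0.95 / 2000))
  # difference is far beyond Monte-Carlo noise for a strong effect
  expect_gt(pc$data$power[1] - pc$data$power[2],
            4 * sqrt(sum(pc$data$mc_se^2)))
})

test_that("a flat scenario yields a flat curve at the test level", {
  p <- scenario_params(theta0 = 0.25, theta1_star = 0.25, n0 = 250)
  pc <- power_curve(p, gamma_grid = c(0, 0.5, 1), replicates = 2000,
                    seed = 4)
  expect_true(all(abs(pc$data$power - 0.05) <
                    4 * sqrt(0.05 * 0.95 / 2000)))
})

test_that("power grows with the per-group sample size", {
  pow_at <- function(n) {
    p <- scenario_params(theta0 = 0.25, delta_t = 3, gamma = 0.3, n0 = n)
    estimate_power(p, replicates = 2000, seed = 5)
  }
  small <- pow_at(100)
  large <- pow_at(1000)
  expect_gt(large$power - small$power,
            4 * sqrt(small$mc_se^2 + large$mc_se^2))
})

test_that("curve input validation rejects bad grids and targets", {
  p <- scenario_params(theta0 = 0.25, delta_t = 3, n0 = 100)
  expect_error(power_curve(p, gamma_grid = numeric(0)), "empty")
  expect_error(power_curve(p, gamma_grid = c(0.5, 0.2)), "increasing")
  expect_error(power_curve(p, gamma_grid = c(0, 1.5)), "gamma_grid")
  pc <- power_curve(p, gamma_grid = c(0, 1), replicates = 200, seed = 1)
  expect_error(max_gamma_for_power(pc, target = 1.2), "target")
})

test_that("thresholding follows the antitonic fit, hand-checked", {
  fake_curve <- function(power) {
    structure(list(
      data = tibble::tibble(gamma = seq(0, 1, by = 0.25), power = power,
                            mc_se = rep(0.01, 5)),
      params = scenario_params(theta0 = 0.25, delta_t = 3, n0 = 100),
      replicates = 2000, seed = 1, yates = FALSE), class = "power_curve")
  }
  # clean monotone curve: largest gamma at or above 0.8 is 0.25
  thr <- max_gamma_for_power(fake_curve(c(0.95, 0.90, 0.70, 0.40, 0.05)))
  expect_equal(thr$gamma_max, 0.25)
  # noisy dip: pooling (0.78, 0.80) -> 0.79 < 0.8, so smoothing stops at 0
  noisy <- c(0.83, 0.78, 0.80, 0.40, 0.05)
  expect_equal(max_gamma_for_power(fake_curve(noisy))$gamma_max, 0)
  # ... while raw thresholding keeps the spurious rebound at gamma 0.5
  expect_equal(max_gamma_for_power(fake_curve(noisy),
                                   smooth = FALSE)$gamma_max, 0.5)
  # everywhere below target: no attainable threshold
  expect_true(is.na(max_gamma_for_power(
    fake_curve(c(0.7, 0.6, 0.5, 0.2, 0.05)))$gamma_max))
})

test_that("a null scenario never attains the target power", {
  p <- scenario_params(theta0 = 0.25, delta_t = 1, n0 = 250)
  pc <- power_curve(p, gamma_grid = seq(0, 1, 0.2), replicates = 1000,
                    seed = 6)
  expect_true(is.na(max_gamma_for_power(pc)$gamma_max))
})

test_that("grid cells reproduce regardless of which grid they sit in", {
  single <- run_table2_grid(delta_values = 3, theta0_values = 0.25,
                            n_values = 100,
                            gamma_grid = seq(0, 1, 0.05),
                            replicates = 500, seed = 9)
  multi <- run_table2_grid(delta_values = c(3, 10),
                           theta0_values = c(0.1, 0.25), n_values = 100,
                           gamma_grid = seq(0, 1, 0.05),
                           replicates = 500, seed = 9)
  expect_identical(
    single$gamma_max,
    multi$gamma_max[multi$delta_t == 3 & multi$theta0 == 0.25])
  expect_error(run_table2_grid(delta_values = numeric(0)), "non-empty")
})

test_that("threshold grids pivot to the wide layout without loss", {
  long <- tibble::tibble(delta_t = c(3, 3, 5, 5),
                         theta0 = c(0.1, 0.25, 0.1, 0.25),
                         n = 100L, gamma_max = c(0.1, 0.2, NA, 0.4))
  wide <- threshold_wide(long)
  expect_equal(names(wide), c("delta_t", "n", "theta0_0.1", "theta0_0.25"))
  expect_equal(wide$theta0_0.25, c(0.2, 0.4))
  expect_true(is.na(wide$theta0_0.1[2]))
})
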