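# Independent textbook oracle for the Pearson statistic: expected counts
# written out cell by cell from the margins, no shared code with the
# package implementation.
oracle_chi2 <- function(m, yates = FALSE) {
  n <- sum(m)
  stat <- 0
  for (i in 1:2) {
    for (j in 1:2) {
      e <- sum(m[i, ]) * sum(m[, j]) / n
      d <- abs(m[i, j] - e)
      if (yates) d <- max(d - 0.5, 0)
      stat <- stat + d^2 / e
    }
  }
  stat
}

# Random 2x2 count tables with non-degenerate margins.
random_tables <- function(n, seed = 1) {
  set.seed(seed)
  replicate(n, {
    repeat {
      m <- matrix(rpois(4, lambda = sample(3:40, 4, replace = TRUE)), 2)
      if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
    }
  }, simplify = FALSE)
}

# Random valid scenarios for property-style loops.
random_scenario <- function(serology = FALSE) {
  scenario_params(
    theta0 = runif(1, 0.05, 0.95),
    delta_t = exp(runif(1, log(0.5), log(8))),
    gamma = runif(1),
    pi_se = if (serology) runif(1, 0.7, 1) else 1,
    pi_sp = if (serology) runif(1, 0.7, 1) else 1,
    n0 = sample(50:400, 1), n1 = sample(50:400, 1))
}
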