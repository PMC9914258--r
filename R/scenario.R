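#' Define a case-control misdiagnosis scenario
#'
#' A scenario bundles every parameter needed to simulate one case-control
#' association study under misdiagnosis: the exposure prevalence in
#' controls (`theta0`, shared by apparent cases), the effect size in
#' genuine cases (either an odds ratio `delta_t` or the genuine-case
#' prevalence `theta1_star` — exactly one of the two), the misdiagnosis
#' rate `gamma`, the sensitivity/specificity of the exposure
#' classification (`pi_se`, `pi_sp`; 1 means the factor is measured
#' perfectly, as in genotyping), the group sizes and the test level.
#'
#' When `delta_t` is supplied, `theta1_star` is derived with
#' [invert_odds_ratio()]; at the degenerate boundaries `theta0 = 0` or
#' `theta0 = 1` the odds ratio is undefined and `theta1_star` is pinned
#' to `theta0` with a warning.
#'
#' @param theta0 Probability of the causal factor being present in
#'   healthy controls (and in apparent cases), in `[0, 1]`.
#' @param delta_t True odds ratio relating genuine cases to controls
#'   (`> 0`).  Mutually exclusive with `theta1_star`.
#' @param theta1_star Probability of the factor being present in genuine
#'   cases, in `[0, 1]`.  Mutually exclusive with `delta_t`.
#' @param gamma Misdiagnosis rate: probability that a diagnosed case is
#'   apparent rather than genuine, in `[0, 1]`.
#' @param pi_se,pi_sp Sensitivity and specificity of the binary
#'   classification of the factor, in `[0, 1]`; both default to 1.
#' @param n0,n1 Number of controls and of diagnosed cases (positive
#'   integers; `n1` defaults to `n0`).
#' @param alpha Significance level of the chi-squared test, in `(0, 1)`.
#'
#' @return An object of class `scenario_params`.
#' @examples
#' scenario_params(theta0 = 0.25, delta_t = 3, gamma = 0.2, n0 = 500)
#' @export
scenario_params <- function(theta0, delta_t = NULL, theta1_star = NULL,
                            gamma = 0, pi_se = 1, pi_sp = 1,
                            n0, n1 = n0, alpha = 0.05) {
  check_prob(theta0, "theta0")
  check_prob(gamma, "gamma")
  check_prob(pi_se, "pi_se")
  check_prob(pi_sp, "pi_sp")
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single number in (0, 1)", call. = FALSE)
  }
  check_count(n0, "n0")
  check_count(n1, "n1")
  if (is.null(delta_t) == is.null(theta1_star)) {
    stop("supply exactly one of `delta_t` or `theta1_star`", call. = FALSE)
  }
  if (is.null(theta1_star)) {
    if (!is.numeric(delta_t) || length(delta_t) != 1L ||
        !is.finite(delta_t) || delta_t <= 0) {
      stop("`delta_t` must be a single finite number > 0", call. = FALSE)
    }
    if (theta0 %in% c(0, 1)) {
      warning("theta0 is at the boundary; odds ratio undefined, ",
              "pinning theta1_star to theta0", call. = FALSE)
      theta1_star <- theta0
    } else {
      theta1_star <- invert_odds_ratio(delta_t, theta0)
    }
  } else {
    check_prob(theta1_star, "theta1_star")
    delta_t <- NA_real_
    if (theta0 > 0 && theta0 < 1 && theta1_star > 0 && theta1_star < 1) {
      delta_t <- (theta1_star / (1 - theta1_star)) / (theta0 / (1 - theta0))
    }
  }
  structure(
    list(theta0 = theta0, delta_t = delta_t, theta1_star = theta1_star,
         gamma = gamma, pi_se = pi_se, pi_sp = pi_sp,
         n0 = as.integer(n0), n1 = as.integer(n1), alpha = alpha),
    class = "scenario_params"
  )
}

#' @export
print.scenario_params <- function(x, ...) {
  cat("Case-control misdiagnosis scenario\n")
  cat(sprintf("  theta0 = %g, theta1* = %g (odds ratio %s)\n",
              x$theta0, x$theta1_star,
              if (is.na(x$delta_t)) "undefined" else format(x$delta_t)))
  cat(sprintf("  gamma = %g, pi_se = %g, pi_sp = %g\n",
              x$gamma, x$pi_se, x$pi_sp))
  cat(sprintf("  n0 = %d controls, n1 = %d cases, alpha = %g\n",
              x$n0, x$n1, x$alpha))
  invisible(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop("`", name, "` must be a probability in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != round(x)) {
    stop("`", name, "` must be a positive integer", call. = FALSE)
  }
  invisible(x)
}

#' Genuine-case exposure probability from an odds ratio
#'
#' Inverts the odds-ratio relation between genuine cases and controls:
#' given the control prevalence `theta0` and the true odds ratio
#' `delta_t`, returns the prevalence `theta1_star` in genuine cases,
#' `delta_t * theta0 / (1 - theta0 + delta_t * theta0)`.  Valid for
#' protective effects (`delta_t < 1`) as well; returns `theta0` itself at
#' the boundaries 0 and 1, where the odds ratio carries no information.
#'
#' @param delta_t Odds ratio, `> 0`.  Vectorised.
#' @param theta0 Control exposure prevalence in `[0, 1]`.  Vectorised.
#' @return Probability of exposure in genuine cases.
#' @examples
#' invert_odds_ratio(3, 0.25)   # 0.5
#' invert_odds_ratio(10, 0.05)  # 10/29
#' @export
invert_odds_ratio <- function(delta_t, theta0) {
  if (!is.numeric(delta_t) || anyNA(delta_t) || any(!is.finite(delta_t)) ||
      any(delta_t <= 0)) {
    stop("`delta_t` must be finite and > 0", call. = FALSE)
  }
  check_prob(theta0, "theta0")
  delta_t * theta0 / (1 - theta0 + delta_t * theta0)
}

#' Marginal exposure probability in diagnosed cases
#'
#' Diagnosed cases are a mixture: a fraction `gamma` are apparent cases
#' carrying the control prevalence `theta0`, the rest are genuine cases
#' with prevalence `theta1_star`.  The marginal probability of the factor
#' being present in a diagnosed case is the convex combination
#' `gamma * theta0 + (1 - gamma) * theta1_star`.
#'
#' @param gamma Misdiagnosis rate in `[0, 1]`.
#' @param theta0 Control (and apparent-case) exposure prevalence.
#' @param theta1_star Genuine-case exposure prevalence.
#' @return Marginal case exposure probability.  All arguments vectorised.
#' @examples
#' case_exposure_prob(0.5, 0.25, 0.5)  # 0.375
#' @export
case_exposure_prob <- function(gamma, theta0, theta1_star) {
  check_prob(gamma, "gamma")
  check_prob(theta0, "theta0")
  check_prob(theta1_star, "theta1_star")
  gamma * theta0 + (1 - gamma) * theta1_star
}

#' Observed-positive probability in cases under imperfect classification
#'
#' Extends [case_exposure_prob()] to a factor measured with sensitivity
#' `pi_se` and specificity `pi_sp` (e.g. a serological cut-off): each of
#' the four latent strata (apparent/genuine crossed with truly
#' exposed/unexposed) contributes observed positives at rate `pi_se` or
#' `1 - pi_sp`.  With `pi_se = pi_sp = 1` this reduces exactly to the
#' perfect-classification mixture.
#'
#' @inheritParams case_exposure_prob
#' @param pi_se,pi_sp Sensitivity and specificity of the classification.
#' @return Probability that a diagnosed case is classified positive.
#' @examples
#' case_exposure_prob_serology(1, 0.25, 0.5, 0.9, 0.9)  # 0.3
#' @export
case_exposure_prob_serology <- function(gamma, theta0, theta1_star,
                                        pi_se = 1, pi_sp = 1) {
  check_prob(gamma, "gamma")
  check_prob(theta0, "theta0")
  check_prob(theta1_star, "theta1_star")
  check_prob(pi_se, "pi_se")
  check_prob(pi_sp, "pi_sp")
  pi_se * gamma * theta0 + (1 - pi_sp) * gamma * (1 - theta0) +
    pi_se * (1 - gamma) * theta1_star +
    (1 - pi_sp) * (1 - gamma) * (1 - theta1_star)
}

#' Observed-positive probability in controls under imperfect classification
#'
#' Controls are truly exposed with probability `theta0`; an imperfect
#' classification observes them positive at rate
#' `pi_se * theta0 + (1 - pi_sp) * (1 - theta0)`.
#'
#' @inheritParams case_exposure_prob_serology
#' @return Probability that a control is classified positive.
#' @examples
#' control_observed_prob(0.25, 0.9, 0.9)  # 0.3
#' @export
control_observed_prob <- function(theta0, pi_se = 1, pi_sp = 1) {
  check_prob(theta0, "theta0")
  check_prob(pi_se, "pi_se")
  check_prob(pi_sp, "pi_sp")
  pi_se * theta0 + (1 - pi_sp) * (1 - theta0)
}
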