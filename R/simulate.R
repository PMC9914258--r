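#' Simulate one observed 2x2 table under a scenario
#'
#' Draws the observed-positive counts directly from the marginal
#' product-binomial sampling model of a case-control design with fixed
#' group sizes: `controls_present ~ Binomial(n0, p0)` and
#' `cases_present ~ Binomial(n1, p1)`, where `p0` is
#' [control_observed_prob()] and `p1` is
#' [case_exposure_prob_serology()] evaluated at the scenario parameters.
#'
#' @param params A [scenario_params()] object.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A [table2x2()].
#' @seealso [sample_latent_table()] for the equivalent hierarchical
#'   sampler over the latent augmented table.
#' @examples
#' p <- scenario_params(theta0 = 0.25, delta_t = 3, gamma = 0.2, n0 = 100)
#' sample_table(p, seed = 1)
#' @export
sample_table <- function(params, seed = NULL) {
  stopifnot(inherits(params, "scenario_params"))
  p0 <- control_observed_prob(params$theta0, params$pi_se, params$pi_sp)
  p1 <- case_exposure_prob_serology(params$gamma, params$theta0,
                                    params$theta1_star,
                                    params$pi_se, params$pi_sp)
  with_seed(seed, {
    a <- stats::rbinom(1L, params$n0, p0)
    c_ <- stats::rbinom(1L, params$n1, p1)
    table2x2(a, params$n0 - a, c_, params$n1 - c_)
  })
}

#' Simulate the latent augmented table under a scenario
#'
#' Samples the full latent structure behind an observed 2x2 table:
#' diagnosed cases are first split into apparent and genuine
#' (`Binomial(n1, gamma)`); true exposure is then drawn per stratum
#' (prevalence `theta0` for apparent cases and controls, `theta1_star`
#' for genuine cases); finally each individual's observed classification
#' is drawn with sensitivity `pi_se` if truly exposed and false-positive
#' rate `1 - pi_sp` otherwise.  Marginalising the result over the latent
#' dimensions gives a table distributed identically to
#' [sample_table()]'s output.
#'
#' @inheritParams sample_table
#' @return An object of class `latent_table`: a list with
#'   \describe{
#'     \item{cases}{3-d integer array `status x true_exposure x observed`
#'       (`apparent`/`genuine`, `exposed`/`unexposed`,
#'       `positive`/`negative`).}
#'     \item{controls}{2-d integer array `true_exposure x observed`.}
#'     \item{params}{the generating scenario.}
#'   }
#' @examples
#' p <- scenario_params(theta0 = 0.25, delta_t = 3, gamma = 0.4,
#'                      pi_se = 0.9, pi_sp = 0.9, n0 = 250)
#' lt <- sample_latent_table(p, seed = 1)
#' marginalize_latent(lt)
#' @export
sample_latent_table <- function(params, seed = NULL) {
  stopifnot(inherits(params, "scenario_params"))
  with_seed(seed, {
    n_app <- stats::rbinom(1L, params$n1, params$gamma)
    n_gen <- params$n1 - n_app
    # true exposure per stratum
    app_exp <- stats::rbinom(1L, n_app, params$theta0)
    gen_exp <- stats::rbinom(1L, n_gen, params$theta1_star)
    ctl_exp <- stats::rbinom(1L, params$n0, params$theta0)
    # observed classification per (stratum, true exposure) cell
    classify <- function(n_exp, n_unexp) {
      pos_e <- stats::rbinom(1L, n_exp, params$pi_se)
      pos_u <- stats::rbinom(1L, n_unexp, 1 - params$pi_sp)
      matrix(as.integer(c(pos_e, pos_u, n_exp - pos_e, n_unexp - pos_u)),
             nrow = 2,
             dimnames = list(true_exposure = c("exposed", "unexposed"),
                             observed = c("positive", "negative")))
    }
    cases <- array(NA_integer_, dim = c(2, 2, 2),
                   dimnames = list(status = c("apparent", "genuine"),
                                   true_exposure = c("exposed", "unexposed"),
                                   observed = c("positive", "negative")))
    cases["apparent", , ] <- classify(app_exp, n_app - app_exp)
    cases["genuine", , ] <- classify(gen_exp, n_gen - gen_exp)
    structure(list(cases = cases,
                   controls = classify(ctl_exp, params$n0 - ctl_exp),
                   params = params),
              class = "latent_table")
  })
}

#' Collapse a latent augmented table to the observed 2x2 table
#'
#' Sums the latent case-status and true-exposure dimensions, keeping the
#' observed classification — the table an analyst would actually see.
#'
#' @param latent A `latent_table` from [sample_latent_table()].
#' @return A [table2x2()] with the scenario's group sizes as column sums.
#' @export
marginalize_latent <- function(latent) {
  stopifnot(inherits(latent, "latent_table"))
  case_pos <- sum(latent$cases[, , "positive"])
  case_neg <- sum(latent$cases[, , "negative"])
  ctl_pos <- sum(latent$controls[, "positive"])
  ctl_neg <- sum(latent$controls[, "negative"])
  table2x2(ctl_pos, ctl_neg, case_pos, case_neg)
}

# Replicate observed-positive counts for R simulated tables at once.
# The marginal product-binomial form keeps cost independent of group
# size, so power curves are cheap even at n = 5000.
sample_counts <- function(params, replicates, gamma = params$gamma) {
  p0 <- control_observed_prob(params$theta0, params$pi_se, params$pi_sp)
  p1 <- case_exposure_prob_serology(gamma, params$theta0,
                                    params$theta1_star,
                                    params$pi_se, params$pi_sp)
  list(ctrl_pos = stats::rbinom(replicates, params$n0, p0),
       case_pos = stats::rbinom(replicates, params$n1, p1))
}
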