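#' Monte-Carlo power of the chi-squared test under a scenario
#'
#' Simulates `replicates` case-control tables from the scenario's
#' product-binomial sampling model and returns the proportion in which
#' Pearson's chi-squared test detects an association (p-value below the
#' scenario's `alpha`), together with its binomial Monte-Carlo standard
#' error `sqrt(p * (1 - p) / R)`.
#'
#' @param params A [scenario_params()] object.
#' @param replicates Number of simulated tables (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @param yates Use the Yates-corrected statistic?  Default `FALSE`.
#' @return A list with `power`, `mc_se`, `replicates`, `alpha`.
#' @examples
#' p <- scenario_params(theta0 = 0.25, delta_t = 3, gamma = 0, n0 = 100)
#' estimate_power(p, replicates = 2000, seed = 1)
#' @export
estimate_power <- function(params, replicates = 10000, seed = NULL,
                           yates = FALSE) {
  stopifnot(inherits(params, "scenario_params"))
  if (!is.numeric(replicates) || replicates < 1) {
    stop("`replicates` must be >= 1", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  rej <- with_seed(seed, {
    cnt <- sample_counts(params, replicates)
    chi2_reject(cnt$ctrl_pos, cnt$case_pos, params$n0, params$n1,
                params$alpha, yates)
  })
  p_hat <- mean(rej)
  list(power = p_hat,
       mc_se = sqrt(p_hat * (1 - p_hat) / replicates),
       replicates = replicates,
       alpha = params$alpha)
}

#' Power as a function of the misdiagnosis rate
#'
#' Estimates power at each value of a misdiagnosis-rate grid (default
#' 0 to 1 in steps of 0.01), holding every other scenario parameter
#' fixed.  Each grid point uses an independent RNG substream derived
#' from `seed`, so estimates do not depend on grid order or subsetting.
#'
#' @inheritParams estimate_power
#' @param gamma_grid Strictly increasing misdiagnosis rates in `[0, 1]`.
#' @return An object of class `power_curve`: a list with a tibble `data`
#'   (columns `gamma`, `power`, `mc_se`), the scenario `params` (its
#'   `gamma` field is ignored), `replicates`, `seed` and `yates`.
#' @examples
#' p <- scenario_params(theta0 = 0.1, delta_t = 10, n0 = 250)
#' pc <- power_curve(p, gamma_grid = c(0, 0.5, 1), replicates = 1000,
#'                   seed = 1)
#' pc$data
#' @export
power_curve <- function(params, gamma_grid = seq(0, 1, by = 0.01),
                        replicates = 10000, seed = NULL, yates = FALSE) {
  stopifnot(inherits(params, "scenario_params"))
  if (length(gamma_grid) == 0) stop("`gamma_grid` is empty", call. = FALSE)
  check_prob(gamma_grid, "gamma_grid")
  if (is.unsorted(gamma_grid, strictly = TRUE)) {
    stop("`gamma_grid` must be strictly increasing", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  pow <- vapply(gamma_grid, function(g) {
    sub <- if (is.null(seed)) NULL else substream_seed(seed, "gamma", g)
    with_seed(sub, {
      cnt <- sample_counts(params, replicates, gamma = g)
      mean(chi2_reject(cnt$ctrl_pos, cnt$case_pos, params$n0, params$n1,
                       params$alpha, yates))
    })
  }, numeric(1))
  structure(
    list(data = tibble::tibble(gamma = gamma_grid, power = pow,
                               mc_se = sqrt(pow * (1 - pow) / replicates)),
         params = params, replicates = replicates, seed = seed,
         yates = yates),
    class = "power_curve"
  )
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("Power curve over %d misdiagnosis rates (R = %d%s)\n",
              nrow(x$data), x$replicates,
              if (isTRUE(x$yates)) ", Yates-corrected" else ""))
  print(x$data, ...)
  invisible(x)
}

#' Largest misdiagnosis rate retaining a target power
#'
#' Scans a [power_curve()] for the largest grid value of the
#' misdiagnosis rate at which the estimated power still meets `target`
#' (80% by default).  Because raw Monte-Carlo estimates fluctuate around
#' a curve that is non-increasing in the misdiagnosis rate, the default
#' first smooths the curve by antitonic (monotone non-increasing)
#' regression, which stabilises the threshold at modest replicate
#' counts; `smooth = FALSE` thresholds the raw estimates.
#'
#' @param curve A [power_curve()].
#' @param target Target power in `(0, 1)`, default 0.80.
#' @param smooth Apply antitonic smoothing before thresholding?
#' @return An object of class `threshold_result`: a list with
#'   `gamma_max` (`NA` when even a misdiagnosis rate of 0 fails the
#'   target), `target`, `smoothed`, and the `curve` augmented with a
#'   `smoothed` power column.
#' @examples
#' p <- scenario_params(theta0 = 0.05, delta_t = 10, n0 = 100)
#' pc <- power_curve(p, replicates = 2000, seed = 1)
#' max_gamma_for_power(pc)
#' @export
max_gamma_for_power <- function(curve, target = 0.80, smooth = TRUE) {
  stopifnot(inherits(curve, "power_curve"))
  if (!is.numeric(target) || length(target) != 1L || target <= 0 ||
      target >= 1) {
    stop("`target` must be in (0, 1)", call. = FALSE)
  }
  dat <- curve$data
  sm <- if (smooth && nrow(dat) > 1L) {
    # isoreg fits non-decreasing; negate to get non-increasing in gamma
    -stats::isoreg(dat$gamma, -dat$power)$yf
  } else {
    dat$power
  }
  curve$data$smoothed <- sm
  hit <- which(sm >= target)
  structure(
    list(gamma_max = if (length(hit)) dat$gamma[max(hit)] else NA_real_,
         target = target, smoothed = smooth, curve = curve),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  if (is.na(x$gamma_max)) {
    cat(sprintf("Target power %.0f%% not reached at any misdiagnosis rate\n",
                100 * x$target))
  } else {
    cat(sprintf("Largest misdiagnosis rate with power >= %.0f%%: %g\n",
                100 * x$target, x$gamma_max))
  }
  invisible(x)
}

threshold_for_scenario <- function(params, gamma_grid, replicates, seed,
                                   yates, target, smooth) {
  pc <- power_curve(params, gamma_grid = gamma_grid,
                    replicates = replicates, seed = seed, yates = yates)
  max_gamma_for_power(pc, target = target, smooth = smooth)
}

#' Misdiagnosis-rate thresholds over an effect-size grid
#'
#' For every combination of true odds ratio, control prevalence and
#' per-group sample size (defaults: the grid spanning weak to strong
#' associations and rare to common factors used throughout the package),
#' runs a full power curve over the misdiagnosis rate and extracts the
#' largest rate retaining the target power, with the factor measured
#' perfectly (`pi_se = pi_sp = 1`).
#'
#' Each cell draws its RNG substream from `seed` hashed with the cell's
#' parameter values, so a subsetted grid reproduces the matching cells
#' of a full run.
#'
#' @param delta_values True odds ratios in genuine cases.
#' @param theta0_values Control exposure prevalences.
#' @param n_values Per-group sample sizes (`n0 = n1`).
#' @param gamma_grid Misdiagnosis-rate grid (default step 0.01).
#' @param replicates Simulated tables per grid point.
#' @param seed Root seed.
#' @param yates Use the Yates-corrected statistic?
#' @param target Target power, default 0.80.
#' @param smooth Antitonic smoothing before thresholding?
#' @param verbose Emit one progress message per cell?
#' @return A tibble with columns `delta_t`, `theta0`, `n`, `gamma_max`
#'   (`NA` when the target power is unattainable).
#' @seealso [threshold_wide()] to pivot to a prevalence-by-odds-ratio
#'   layout.
#' @export
run_table2_grid <- function(delta_values = c(1.25, 1.5, 2, 3, 5, 10),
                            theta0_values = c(0.05, 0.1, 0.25, 0.5),
                            n_values = c(100, 250, 500, 1000, 2500, 5000),
                            gamma_grid = seq(0, 1, by = 0.01),
                            replicates = 10000, seed = NULL,
                            yates = FALSE, target = 0.80, smooth = TRUE,
                            verbose = FALSE) {
  if (!length(delta_values) || !length(theta0_values) || !length(n_values)) {
    stop("all parameter grids must be non-empty", call. = FALSE)
  }
  cells <- expand.grid(n = n_values, theta0 = theta0_values,
                       delta_t = delta_values)[, 3:1]
  gamma_max <- vapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    if (verbose) {
      message(sprintf("[table2] odds ratio %g, theta0 %g, n %d",
                      cl$delta_t, cl$theta0, as.integer(cl$n)))
    }
    sub <- if (is.null(seed)) NULL else
      substream_seed(seed, "table2", cl$delta_t, cl$theta0, cl$n)
    params <- scenario_params(theta0 = cl$theta0, delta_t = cl$delta_t,
                              n0 = cl$n)
    threshold_for_scenario(params, gamma_grid, replicates, sub, yates,
                           target, smooth)$gamma_max
  }, numeric(1))
  tibble::tibble(delta_t = cells$delta_t, theta0 = cells$theta0,
                 n = as.integer(cells$n), gamma_max = gamma_max)
}

#' Misdiagnosis-rate thresholds over a classification-accuracy grid
#'
#' As [run_table2_grid()], but for a fixed association (default odds
#' ratio 3, control prevalence 0.25) while the sensitivity and
#' specificity of the factor's classification vary — the setting of a
#' serological association study with an imperfect cut-off.
#'
#' @param pi_se_values,pi_sp_values Sensitivities and specificities of
#'   the classification.
#' @param n_values Per-group sample sizes.
#' @param delta_t,theta0 Fixed association parameters.
#' @inheritParams run_table2_grid
#' @return A tibble with columns `pi_se`, `pi_sp`, `n`, `gamma_max`.
#' @export
run_table3_grid <- function(pi_se_values = c(1, 0.975, 0.925, 0.9, 0.8),
                            pi_sp_values = c(1, 0.975, 0.925, 0.9, 0.8),
                            n_values = c(100, 250, 500, 1000, 2500, 5000),
                            delta_t = 3, theta0 = 0.25,
                            gamma_grid = seq(0, 1, by = 0.01),
                            replicates = 10000, seed = NULL,
                            yates = FALSE, target = 0.80, smooth = TRUE,
                            verbose = FALSE) {
  if (!length(pi_se_values) || !length(pi_sp_values) || !length(n_values)) {
    stop("all parameter grids must be non-empty", call. = FALSE)
  }
  cells <- expand.grid(n = n_values, pi_sp = pi_sp_values,
                       pi_se = pi_se_values)[, 3:1]
  gamma_max <- vapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    if (verbose) {
      message(sprintf("[table3] pi_se %g, pi_sp %g, n %d",
                      cl$pi_se, cl$pi_sp, as.integer(cl$n)))
    }
    sub <- if (is.null(seed)) NULL else
      substream_seed(seed, "table3", cl$pi_se, cl$pi_sp, cl$n)
    params <- scenario_params(theta0 = theta0, delta_t = delta_t,
                              pi_se = cl$pi_se, pi_sp = cl$pi_sp,
                              n0 = cl$n)
    threshold_for_scenario(params, gamma_grid, replicates, sub, yates,
                           target, smooth)$gamma_max
  }, numeric(1))
  tibble::tibble(pi_se = cells$pi_se, pi_sp = cells$pi_sp,
                 n = as.integer(cells$n), gamma_max = gamma_max)
}

#' Pivot a long threshold table to a wide layout
#'
#' Spreads one parameter across columns (by default `theta0` for
#' effect-size grids and `pi_se` for classification grids), keeping one
#' row per remaining parameter combination — the layout in which such
#' threshold tables are usually printed.
#'
#' @param thresholds A tibble from [run_table2_grid()] or
#'   [run_table3_grid()].
#' @param names_from Column to spread; guessed from the input if `NULL`.
#' @return A wide tibble; unattainable thresholds stay `NA`.
#' @export
threshold_wide <- function(thresholds, names_from = NULL) {
  if (is.null(names_from)) {
    names_from <- if ("theta0" %in% names(thresholds)) "theta0"
                  else if ("pi_se" %in% names(thresholds)) "pi_se"
                  else stop("cannot guess the column to spread", call. = FALSE)
  }
  tidyr::pivot_wider(thresholds, names_from = tidyr::all_of(names_from),
                     values_from = "gamma_max",
                     names_prefix = paste0(names_from, "_"))
}
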