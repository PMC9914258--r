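#' Bundled parameter sets from two published ME/CFS studies
#'
#' Loads the transcribed summary parameters of two case-control studies
#' shipped with the package:
#' \describe{
#'   \item{`"steiner_snps"`}{a candidate-gene study of five SNPs
#'     (201 controls, 305 cases with an infectious disease trigger);
#'     allele frequencies in controls and allele-based odds ratios, with
#'     genotyping assumed error-free (`pi_se = pi_sp = 1`).  Because the
#'     reported prevalences are allele frequencies, each subject
#'     contributes two independent allele copies to the simulated
#'     tables (`copies_per_subject = 2`).}
#'   \item{`"cliff_serology"`}{seroprevalence of antibodies against six
#'     herpesviruses (107 controls, 251 severely affected cases); the
#'     original seropositivity cut-offs followed the 2-sigma rule, whose
#'     expected specificity under a normal seronegative population is
#'     about 0.975, so `pi_se = pi_sp = 0.975`.}
#' }
#' The printed 95% confidence intervals and p-values are carried along
#' for provenance; simulations use only `theta0`, `delta_t`, the group
#' sizes and `pi_se`/`pi_sp`.
#'
#' @param name `"steiner_snps"` or `"cliff_serology"`.
#' @return A tibble with one row per study factor.
#' @examples
#' load_study_fixtures("steiner_snps")
#' @export
load_study_fixtures <- function(name = c("steiner_snps", "cliff_serology")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "misdiagpower", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Power curves for a set of study factors
#'
#' Runs one misdiagnosis-rate power curve per factor (SNP or antibody),
#' using each factor's own control prevalence, odds ratio, group sizes
#' and classification accuracy.  Protective factors (odds ratio below 1)
#' are handled by the same odds-ratio inversion, which simply yields a
#' genuine-case prevalence below the control one.  When `theta0` is an
#' allele frequency, the binomial denominators are the allele counts
#' `copies_per_subject * n0` and `copies_per_subject * n1` rather than
#' the subject counts (2 copies per subject for autosomal SNPs; a
#' missing column means 1, i.e. one observation per subject).
#'
#' @param factors A tibble as returned by [load_study_fixtures()]
#'   (columns `label`, `theta0`, `delta_t`, `n0`, `n1`, `pi_se`,
#'   `pi_sp`, optionally `copies_per_subject`).
#' @inheritParams power_curve
#' @return A named list of [power_curve()] objects, one per factor.
#' @examples
#' snps <- load_study_fixtures("steiner_snps")
#' curves <- study_power_curves(snps[1, ], gamma_grid = c(0, 0.5, 1),
#'                              replicates = 500, seed = 1)
#' @export
study_power_curves <- function(factors, gamma_grid = seq(0, 1, by = 0.01),
                               replicates = 10000, seed = NULL,
                               yates = FALSE) {
  needed <- c("label", "theta0", "delta_t", "n0", "n1", "pi_se", "pi_sp")
  missing_cols <- setdiff(needed, names(factors))
  if (length(missing_cols)) {
    stop("`factors` lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(factors$copies_per_subject)) factors$copies_per_subject <- 1L
  curves <- lapply(seq_len(nrow(factors)), function(i) {
    f <- factors[i, ]
    params <- scenario_params(theta0 = f$theta0, delta_t = f$delta_t,
                              pi_se = f$pi_se, pi_sp = f$pi_sp,
                              n0 = f$copies_per_subject * f$n0,
                              n1 = f$copies_per_subject * f$n1)
    sub <- if (is.null(seed)) NULL else substream_seed(seed, "study", f$label)
    power_curve(params, gamma_grid = gamma_grid, replicates = replicates,
                seed = sub, yates = yates)
  })
  stats::setNames(curves, factors$label)
}

#' Odds ratio of a 2x2 table with a Woolf confidence interval
#'
#' Computes the cross-product odds ratio `(a d) / (b c)` comparing cases
#' to controls, with a log-normal (Woolf) confidence interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.  When any cell is
#' zero, the Haldane–Anscombe correction adds 0.5 to every cell and the
#' result is flagged as `corrected`.  Mainly a convenience for checking
#' transcribed study parameters against their printed intervals.
#'
#' @param table A [table2x2()] or 2x2 count matrix.
#' @param level Confidence level, default 0.95.
#' @return A list with `or`, `lower`, `upper`, `level`, `corrected`.
#' @examples
#' odds_ratio_with_ci(table2x2(10, 20, 20, 10))
#' @export
odds_ratio_with_ci <- function(table, level = 0.95) {
  tab <- as_table2x2(table)
  if (sum(tab) == 0) stop("table has no observations", call. = FALSE)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("`level` must be in (0, 1)", call. = FALSE)
  }
  corrected <- any(tab == 0)
  x <- as.numeric(tab) + if (corrected) 0.5 else 0
  # x = (ctrl_pos, ctrl_neg, case_pos, case_neg)
  or <- (x[3] * x[2]) / (x[1] * x[4])
  se <- sqrt(sum(1 / x))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = or, lower = or * exp(-z * se), upper = or * exp(z * se),
       level = level, corrected = corrected)
}
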