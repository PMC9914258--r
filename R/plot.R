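#' Plot power against the misdiagnosis rate
#'
#' Draws one or several power curves with dashed reference lines at the
#' target power and at the test level — the standard way to read off,
#' at a glance, how much misdiagnosis a design tolerates.  Requires
#' ggplot2.
#'
#' @param curves A single [power_curve()] or a named list of them (as
#'   returned by [study_power_curves()]).
#' @param target Target power drawn as the upper dashed line.
#' @param alpha Test level drawn as the lower dashed line; taken from
#'   the first curve's scenario if `NULL`.
#' @return A ggplot object.
#' @export
plot_power_curves <- function(curves, target = 0.80, alpha = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  if (inherits(curves, "power_curve")) curves <- list(power = curves)
  if (is.null(alpha)) alpha <- curves[[1]]$params$alpha
  dat <- do.call(rbind, lapply(names(curves), function(lb) {
    cbind(label = lb, curves[[lb]]$data[, c("gamma", "power")])
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = gamma, y = power,
                                    colour = label)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = target, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "misdiagnosis rate",
                  y = "power to detect the association",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
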