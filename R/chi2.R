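#' Build a 2x2 case-control contingency table
#'
#' Rows are factor Present/Absent, columns Controls/Cases.
#'
#' @param controls_present,controls_absent,cases_present,cases_absent
#'   Non-negative integer counts.
#' @return A 2x2 integer matrix of class `table2x2`.
#' @examples
#' table2x2(10, 20, 20, 10)
#' @export
table2x2 <- function(controls_present, controls_absent,
                     cases_present, cases_absent) {
  counts <- c(controls_present, controls_absent, cases_present, cases_absent)
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(
    matrix(as.integer(counts), nrow = 2,
           dimnames = list(factor = c("present", "absent"),
                           group = c("controls", "cases"))),
    class = c("table2x2", "matrix", "array")
  )
}

as_table2x2 <- function(x) {
  if (inherits(x, "table2x2")) return(x)
  x <- as.matrix(x)
  if (!all(dim(x) == c(2L, 2L))) {
    stop("expected a 2x2 table", call. = FALSE)
  }
  table2x2(x[1, 1], x[2, 1], x[1, 2], x[2, 2])
}

#' Pearson's chi-squared test on a 2x2 table
#'
#' Computes the classical Pearson statistic `sum((O - E)^2 / E)` with
#' expected counts from the row/column margins, and its p-value from the
#' chi-squared distribution with 1 degree of freedom.  With
#' `yates = TRUE` the absolute deviations are shrunk by 0.5 (floored at
#' zero) before squaring, matching the continuity-corrected variant.
#'
#' A table with an empty row or column margin leaves the test undefined;
#' such tables carry no evidence against the null of no association and
#' are reported as `p_value = 1` with `degenerate = TRUE`, so that power
#' estimates remain defined for every simulated replicate.
#'
#' @param table A [table2x2()] or any 2x2 matrix of counts (column 1 =
#'   controls, row 1 = factor present).
#' @param yates Apply the Yates continuity correction?  Default `FALSE`:
#'   the uncorrected, classical statistic.
#' @return A list with `statistic`, `p_value`, `df` (always 1) and
#'   `degenerate`.
#' @examples
#' pearson_chi2(table2x2(10, 20, 20, 10))  # statistic 20/3
#' @export
pearson_chi2 <- function(table, yates = FALSE) {
  tab <- as_table2x2(table)
  o <- as.numeric(tab)
  n <- sum(o)
  if (n <= 0) stop("table has no observations", call. = FALSE)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    return(list(statistic = NA_real_, p_value = 1, df = 1L,
                degenerate = TRUE))
  }
  e <- outer(rs, cs) / n
  dev <- abs(tab - e)
  if (yates) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / e)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, degenerate = FALSE)
}

# Vectorised rejection indicator over replicate tables with fixed group
# sizes: ctrl_pos / case_pos are vectors of observed-positive counts.
# Uses the N(ad - bc)^2 / (r1 r2 c1 c2) shortcut (with the Yates variant
# N(|ad - bc| - N/2)^2, floored); degenerate row margins never reject.
chi2_reject <- function(ctrl_pos, case_pos, n0, n1, alpha, yates = FALSE) {
  a <- as.numeric(ctrl_pos)
  c_ <- as.numeric(case_pos)
  n0 <- as.numeric(n0)
  n1 <- as.numeric(n1)
  nn <- n0 + n1
  r1 <- a + c_
  r2 <- nn - r1
  num <- abs(a * (n1 - c_) - (n0 - a) * c_)
  if (yates) num <- pmax(num - nn / 2, 0)
  stat <- nn * num^2 / (r1 * r2 * n0 * n1)
  reject <- stats::pchisq(stat, df = 1, lower.tail = FALSE) < alpha
  reject[r1 == 0 | r2 == 0] <- FALSE
  reject
}
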