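#' Ordinary least-squares linear correlation
#'
#' Fits y = slope * x + intercept by OLS (via [stats::lm()]) and reports
#' the coefficient of determination R^2 = 1 - SS_res / SS_tot. Used for
#' the structure-property correlations, e.g. LE-CT energy gap against
#' the inter-ring distance, or CT population after 100 fs against
#' d_Zn-Zn + d_P-P. When y is constant SS_tot = 0 and R^2 is reported
#' as 0 by convention (no variance to explain).
#'
#' @param x,y numeric vectors (>= 3 points; x must not be constant).
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
linear_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("at least 3 points are required", call. = FALSE)
  if (stats::sd(x) == 0) stop("x is constant: fit undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, n = length(x))
}
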