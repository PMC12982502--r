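#' Quadratic-plateau mean function
#'
#' Piecewise dose-response mean used throughout the package: quadratic in the
#' nitrogen rate up to the breakpoint `beta1 / (2 * beta2)` and constant at
#' the plateau value `beta0 + beta1^2 / (4 * beta2)` beyond it. The function
#' is continuous at the breakpoint (the quadratic attains its maximum there),
#' so the plateau is exactly the maximum of the quadratic arm.
#'
#' @param x Nitrogen rate(s), kg N ha^-1. Vectorized.
#' @param beta0 Intercept: response at zero N (kg ha^-1).
#' @param beta1 Linear coefficient (kg response per kg N). Must be >= 0.
#' @param beta2 Quadratic curvature (kg response per (kg N)^2). Must be > 0.
#'   The mean is `beta0 + beta1 * x - beta2 * x^2` below the breakpoint.
#' @return Numeric vector of mean responses, same length as `x` (recycled
#'   against the parameter vectors).
#' @examples
#' qp_mean(c(0, 100, 200, 315), beta0 = 9000, beta1 = 60, beta2 = 0.15)
#' @export
qp_mean <- function(x, beta0, beta1, beta2) {
  if (any(beta2 <= 0)) stop("beta2 must be > 0 for a quadratic-plateau mean")
  bp <- beta1 / (2 * beta2)
  plateau <- beta0 + beta1 * bp - beta2 * bp^2
  ifelse(x < bp, beta0 + beta1 * x - beta2 * x^2, plateau)
}

#' Breakpoint (agronomic optimum) of a quadratic-plateau curve
#'
#' @inheritParams qp_mean
#' @return `beta1 / (2 * beta2)`, the N rate at which the quadratic arm
#'   peaks and the plateau begins.
#' @export
qp_breakpoint <- function(beta1, beta2) beta1 / (2 * beta2)
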