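#' Four-parameter logistic curve along the flow axis
#'
#' Evaluates `y = (A1 - A2) / (1 + exp((x - X0) / D)) + A2` at positions
#' `x`. `A1` is the plateau approached for `x << X0` (the downstream end,
#' part index 1, for `D > 0`), `A2` the plateau for `x >> X0`, `X0` the
#' inflection point in part-index units and `D` the scale controlling the
#' steepness of the transition.
#'
#' @param x numeric vector of positions (part indices, usually 1..50).
#' @param A1,A2 plateau values (dimensionless, normalized fluorescence).
#' @param X0 inflection point, in part-index units.
#' @param D slope-scale parameter, in part-index units; must be non-zero.
#' @return numeric vector of curve values, same length as `x`.
#' @seealso [logistic_slope()] for the analytic first derivative,
#'   [fit_logistic()] to estimate the parameters from a profile.
#' @export
#' @examples
#' logistic_curve(1:50, A1 = 2, A2 = 1, X0 = 15, D = 3)
logistic_curve <- function(x, A1, A2, X0, D) {
  stopifnot(is.numeric(x), D != 0)
  (A1 - A2) / (1 + exp((x - X0) / D)) + A2
}

#' Analytic first derivative of the logistic curve
#'
#' The slope of [logistic_curve()] at positions `x`:
#' `y'(x) = -(A1 - A2) * u / (D * (1 + u)^2)` with `u = exp((x - X0)/D)`.
#' At the inflection point this reduces to `(A2 - A1) / (4 D)`.
#'
#' @inheritParams logistic_curve
#' @return numeric vector of slopes.
#' @export
logistic_slope <- function(x, A1, A2, X0, D) {
  stopifnot(is.numeric(x), D != 0)
  u <- exp((x - X0) / D)
  ## guard u = Inf: slope tends to 0 in both tails
  s <- -(A1 - A2) * u / (D * (1 + u)^2)
  s[!is.finite(u)] <- 0
  s
}
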