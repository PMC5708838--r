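#' Fit the logistic polarity model to a flow-axis profile
#'
#' Nonlinear least squares of
#' `y = (A1 - A2)/(1 + exp((x - X0)/D)) + A2` over `x = 1..length(y)` by
#' Levenberg-Marquardt. Initial values are `A1 = y[1]`, `A2 = y[n]`, `X0` at
#' the largest finite-difference gradient and `D = 2`; on failure up to
#' `max_restarts` jittered re-initializations are tried (the jitter RNG is
#' seeded internally, so fitting is deterministic and leaves the global RNG
#' state untouched). A near-constant profile that defeats the optimizer is
#' returned as the exact degenerate fit `A1 = A2 = mean(y)`.
#'
#' @param profile numeric vector (normalized flow-axis profile; 50 parts in
#'   the standard pipeline), all finite.
#' @param max_restarts maximum jittered re-initializations after the
#'   deterministic start fails.
#' @return an object of class `logistic_fit`: list with `A1`, `A2`, `X0`,
#'   `D`, `residual_sse`, `converged`. If no start converges, an error of
#'   class `flowpol_fit_failure` is signalled carrying the best attempt in
#'   its `fit` field.
#' @export
fit_logistic <- function(profile, max_restarts = 5L) {
  y <- as.numeric(profile)
  if (any(!is.finite(y))) stop("profile must be finite", call. = FALSE)
  n <- length(y)
  x <- seq_len(n)

  if (stats::sd(y) < 1e-9)
    return(structure(list(A1 = mean(y), A2 = mean(y), X0 = (n + 1) / 2,
                          D = 2, residual_sse = sum((y - mean(y))^2),
                          converged = TRUE),
                     class = "logistic_fit"))

  g <- abs(diff(y))
  start0 <- list(A1 = y[1], A2 = y[n],
                 X0 = as.numeric(which.max(g)) + 0.5, D = 2)
  resid_fn <- function(p) {
    y - ((p[1] - p[2]) / (1 + exp((x - p[3]) / p[4])) + p[2])
  }
  try_fit <- function(st) {
    tryCatch({
      fit <- minpack.lm::nls.lm(
        par = unlist(st), fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 500))
      if (!fit$info %in% 1:4) return(NULL)
      cf <- fit$par
      if (!all(is.finite(cf)) || abs(cf[["D"]]) < 1e-9) return(NULL)
      structure(list(A1 = cf[["A1"]], A2 = cf[["A2"]], X0 = cf[["X0"]],
                     D = cf[["D"]], residual_sse = fit$deviance,
                     converged = TRUE),
                class = "logistic_fit")
    }, error = function(e) NULL)
  }

  ## deterministic starts: gradient-based, then gentle-slope fallbacks that
  ## behave well on near-flat profiles where the gradient start is singular
  starts <- list(
    start0,
    list(A1 = max(y), A2 = min(y), X0 = (n + 1) / 2, D = 10),
    list(A1 = min(y), A2 = max(y), X0 = (n + 1) / 2, D = 10),
    list(A1 = y[1], A2 = y[n], X0 = start0$X0, D = -2))
  for (st in starts) {
    fit <- try_fit(st)
    if (!is.null(fit)) return(fit)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(20231107L)
  best <- NULL
  for (k in seq_len(max_restarts)) {
    st <- list(A1 = start0$A1 * stats::runif(1, 0.5, 1.5) +
                 stats::rnorm(1, 0, 0.1),
               A2 = start0$A2 * stats::runif(1, 0.5, 1.5) +
                 stats::rnorm(1, 0, 0.1),
               X0 = stats::runif(1, 2, n - 1),
               D = sample(c(-1, 1), 1) * stats::runif(1, 0.5, 8))
    fit <- try_fit(st)
    if (!is.null(fit)) {
      if (is.null(best) || fit$residual_sse < best$residual_sse) best <- fit
    }
  }
  if (!is.null(best)) return(best)
  cond <- errorCondition("fit failure: logistic fit did not converge",
                         class = c("flowpol_fit_failure", "error"),
                         fit = structure(c(start0,
                                           list(residual_sse = NA_real_,
                                                converged = FALSE)),
                                         class = "logistic_fit"))
  stop(cond)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "logistic_fit: A1 = %.4g, A2 = %.4g, X0 = %.4g, D = %.4g (SSE %.3g)\n",
    x$A1, x$A2, x$X0, x$D, x$residual_sse))
  invisible(x)
}

#' Slope of the fitted curve at its inflection point
#'
#' The analytic derivative of the logistic at `X0` reduces to
#' `(A2 - A1) / (4 D)`; negative for a downstream-high profile.
#'
#' @param fit a converged [fit_logistic()].
#' @return slope, dimensionless per part.
#' @export
inflection_slope <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (fit$D == 0) stop("degenerate fit: D = 0", call. = FALSE)
  (fit$A2 - fit$A1) / (4 * fit$D)
}

#' Onset position of polarity
#'
#' Scans integer positions `x = 2, 3, ...` from the downstream end and
#' returns the first `x` whose analytic slope magnitude (or that at
#' `x + 1`) has dropped below `threshold` while the slope magnitude at
#' `x - 1` has not: the position where the polarized transition flattens
#' out. Returns `NA` when no position qualifies (e.g. a flat fit, whose
#' slope is below threshold everywhere).
#'
#' @param fit a converged [fit_logistic()].
#' @param threshold slope magnitude cutoff (default 0.005).
#' @param n_bins number of parts scanned (default 50).
#' @return integer part index in `2..(n_bins - 1)`, or `NA_integer_`.
#' @export
detect_onset <- function(fit, threshold = 0.005, n_bins = 50L) {
  stopifnot(inherits(fit, "logistic_fit"))
  s <- abs(logistic_slope(seq_len(n_bins), fit$A1, fit$A2, fit$X0, fit$D))
  for (x in 2:(n_bins - 1L)) {
    if ((s[x] < threshold || s[x + 1L] < threshold) && s[x - 1L] >= threshold)
      return(as.integer(x))
  }
  NA_integer_
}

#' Polarity metrics of one fitted profile
#'
#' @param fit a converged [fit_logistic()].
#' @param threshold onset slope cutoff, passed to [detect_onset()].
#' @param n_bins number of parts.
#' @return list with `range` (`|A1 - A2|`), `onset` (integer part or `NA`)
#'   and `slope` (`(A2 - A1)/(4 D)`).
#' @export
polarity_metrics <- function(fit, threshold = 0.005, n_bins = 50L) {
  list(range = abs(fit$A1 - fit$A2),
       onset = detect_onset(fit, threshold, n_bins),
       slope = inflection_slope(fit))
}

#' Polarity metrics of one cell's spatiotemporal map
#'
#' Extracts the requested minute's row (by default minute 30, when the
#' polarized distribution has become steady), fits the logistic model and
#' returns the three polarity statistics together with the fit.
#'
#' @param map an `st_map` from [quantify_stack()] or [average_maps()].
#' @param minute minute after flow onset whose row is fitted.
#' @param threshold onset slope cutoff.
#' @return list with `range`, `onset`, `slope`, and `fit`.
#' @export
cell_metrics <- function(map, minute = 30, threshold = 0.005) {
  stopifnot(inherits(map, "st_map"))
  i <- which(abs(map$times - minute * 60) < 1e-9)
  if (length(i) != 1L)
    stop("invalid argument: map has no row at minute ", minute, call. = FALSE)
  fit <- fit_logistic(map$matrix[i, ])
  c(polarity_metrics(fit, threshold, n_bins = ncol(map$matrix)),
    list(fit = fit))
}
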