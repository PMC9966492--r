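#' Fit the Sisko model to a flow curve
#'
#' Least squares on log-viscosity (which balances residuals across the three
#' decades of shear rate a flow curve spans), minimized with the
#' Levenberg-Marquardt algorithm under box constraints `mu0 >= 0`, `k >= 0`;
#' the flow index `n` is free in sign. Starting values follow the shape of
#' the model: `mu0` from the highest-shear point, `k` from the low-shear
#' excess over that plateau, `n = 0`.
#'
#' The default fitting window is 0.1-10 1/s, the shear range over which the
#' Sisko law approximates these agents well; the model is not recommended
#' above 10 1/s, where viscosity is effectively a (temperature-dependent)
#' constant.
#'
#' @param curve A [rheometry_curve].
#' @param shear_window Numeric length-2 interval of shear rates (1/s) to fit
#'   on, or `NULL` for the full curve. Default `c(0.1, 10)`.
#' @return Object of class `sisko_fit`: a list with `params`
#'   (a [sisko_params]), `residual` (residual norm in log-viscosity),
#'   `converged` (logical), `n_points`, and `shear_window`.
#' @examples
#' p <- embolic_sisko_params("onyx18", 20)
#' cu <- generate_curve(synthetic_rheometry_config(p, noise_sd = 0))
#' fit_sisko(cu)$params
#' @export
fit_sisko <- function(curve, shear_window = c(0.1, 10)) {
  stopifnot(inherits(curve, "rheometry_curve"))
  U <- curve$shear_rates; mu <- curve$viscosities
  if (!is.null(shear_window)) {
    if (length(shear_window) != 2 || shear_window[1] >= shear_window[2])
      stop("`shear_window` must be an increasing length-2 interval")
    keep <- U >= shear_window[1] & U <= shear_window[2]
    U <- U[keep]; mu <- mu[keep]
  }
  if (length(U) < 4)
    stop("need at least 4 points in the fitting window, got ", length(U))

  lmu <- log(mu)
  mu0_0 <- mu[which.max(U)]
  k0 <- max(mu[which.min(U)] - mu0_0, 1e-3)
  resid_fn <- function(th) {
    log(pmax(th[1] + th[2] * U^(th[3] - 1), .Machine$double.xmin)) - lmu
  }
  out <- tryCatch(
    minpack.lm::nls.lm(
      par = c(mu0 = mu0_0, k = k0, n = 0), fn = resid_fn,
      lower = c(0, 0, -Inf), upper = c(Inf, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500,
                                           ftol = 1e-15, ptol = 1e-15)),
    error = function(e) {
      stop("Sisko fit failed for '", curve$polymer_label, "': ",
           conditionMessage(e))
    })
  converged <- out$info %in% 1:4
  if (!converged && out$info == 0)
    stop("Sisko fit: invalid input to the optimizer (info = 0); ",
         "message: ", out$message)
  params <- sisko_params(out$par[["mu0"]], out$par[["k"]], out$par[["n"]],
                         temperature = curve$temperature,
                         polymer_label = curve$polymer_label)
  structure(list(params = params,
                 residual = sqrt(out$deviance),
                 converged = converged,
                 n_points = length(U),
                 shear_window = shear_window,
                 optimizer_message = out$message),
            class = "sisko_fit")
}

#' @export
print.sisko_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  fit on %d points, residual norm (log space) %.3g, %s\n",
              x$n_points, x$residual,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Continuous piecewise log-linear approximation of a flow curve
#'
#' Approximates log10(viscosity) as a continuous piecewise-linear function of
#' log10(shear rate): the representation used to feed measured flow curves
#' into CFD solvers, with the curve divided into segments at the given
#' breakpoints. Continuity is built into the linear-spline basis
#' (intercept, slope, and one hinge term per breakpoint), so ordinary least
#' squares yields the residual-minimizing continuous fit. Outside the data
#' range evaluation continues along the end segments.
#'
#' @param curve A [rheometry_curve].
#' @param breakpoints Interior breakpoint shear rates, 1/s (default
#'   `c(1, 10)`, separating the low-shear pseudoplastic range, the
#'   transition, and the near-constant high-shear range). May be empty (a
#'   single straight line) or any strictly increasing set; every resulting
#'   segment must contain at least 2 data points.
#' @return Object of class `piecewise_loglin` with elements `breakpoints`,
#'   `coef` (intercept, slope, hinge increments) and `residual`
#'   (residual norm in log10 viscosity).
#' @seealso [eval_piecewise()]
#' @export
fit_piecewise <- function(curve, breakpoints = c(1, 10)) {
  stopifnot(inherits(curve, "rheometry_curve"))
  breakpoints <- sort(as.numeric(breakpoints))
  if (any(breakpoints <= 0)) stop("breakpoints must be positive shear rates")
  if (any(diff(breakpoints) <= 0)) stop("breakpoints must be distinct")
  x <- log10(curve$shear_rates); y <- log10(curve$viscosities)
  bp <- log10(breakpoints)
  edges <- c(-Inf, bp, Inf)
  seg <- findInterval(x, edges)
  counts <- tabulate(seg, nbins = length(edges) - 1)
  if (any(counts < 2))
    stop("each segment must contain at least 2 points; segment counts: ",
         paste(counts, collapse = ", "))
  X <- cbind(intercept = 1, slope = x)
  for (t in bp) X <- cbind(X, pmax(x - t, 0))
  fit <- stats::lm.fit(X, y)
  structure(list(breakpoints = breakpoints,
                 coef = unname(fit$coefficients),
                 residual = sqrt(sum(fit$residuals^2)),
                 n_points = length(x)),
            class = "piecewise_loglin")
}

#' Evaluate a piecewise log-linear viscosity approximation
#'
#' @param fit A `piecewise_loglin` object from [fit_piecewise()].
#' @param shear_rate Shear rate(s), 1/s, strictly positive.
#' @return Viscosity in mPa.s.
#' @export
eval_piecewise <- function(fit, shear_rate) {
  stopifnot(inherits(fit, "piecewise_loglin"))
  shear_rate <- as.numeric(shear_rate)
  if (any(!is.finite(shear_rate)) || any(shear_rate <= 0))
    stop("`shear_rate` must be finite and strictly positive")
  x <- log10(shear_rate)
  y <- fit$coef[1] + fit$coef[2] * x
  bp <- log10(fit$breakpoints)
  if (length(bp))
    for (i in seq_along(bp)) y <- y + fit$coef[2 + i] * pmax(x - bp[i], 0)
  10^y
}

#' @export
print.piecewise_loglin <- function(x, ...) {
  cat(sprintf(
    "Piecewise log-linear viscosity fit: %d segment(s), breakpoints {%s} 1/s\n",
    length(x$breakpoints) + 1, paste(format(x$breakpoints), collapse = ", ")))
  cat(sprintf("  residual norm (log10 space) %.3g on %d points\n",
              x$residual, x$n_points))
  invisible(x)
}
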