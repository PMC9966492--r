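#' Sisko constitutive parameters
#'
#' The Sisko model describes a shear-thinning fluid with a Newtonian plateau
#' at high shear:
#' \deqn{\mu_{eff}(U) = \mu_0 + k U^{\,n-1}}
#' with effective viscosity in mPa.s and shear rate \eqn{U} in 1/s.
#' `mu0` is the limiting viscosity at high shear, `k` the consistency
#' coefficient (mPa.s.s^(n-1)) and `n` the dimensionless flow index
#' (unconstrained in sign; the published 20 degC constants are slightly
#' negative).
#'
#' @param mu0 Limiting high-shear viscosity, mPa.s; must be >= 0.
#' @param k Consistency coefficient, mPa.s.s^(n-1); must be >= 0.
#' @param n Flow index, dimensionless.
#' @param temperature Temperature the constants refer to, degC.
#' @param polymer_label Free-text sample label.
#' @return Object of class `sisko_params`.
#' @seealso [eval_sisko()], [fit_sisko()], [embolic_sisko_params()]
#' @export
sisko_params <- function(mu0, k, n, temperature = NA_real_, polymer_label = "") {
  mu0 <- as.numeric(mu0)[1]; k <- as.numeric(k)[1]; n <- as.numeric(n)[1]
  temperature <- as.numeric(temperature)[1]
  if (!is.finite(mu0) || mu0 < 0) stop("`mu0` must be finite and >= 0")
  if (!is.finite(k) || k < 0) stop("`k` must be finite and >= 0")
  if (!is.finite(n)) stop("`n` must be finite")
  if (!is.na(temperature) && !is.finite(temperature))
    stop("`temperature` must be finite")
  structure(list(mu0 = mu0, k = k, n = n, temperature = temperature,
                 polymer_label = as.character(polymer_label)[1]),
            class = "sisko_params")
}

#' @export
print.sisko_params <- function(x, ...) {
  lab <- if (nzchar(x$polymer_label)) x$polymer_label else "<unlabelled>"
  cat(sprintf("Sisko viscosity law: %s at %s degC\n", lab,
              format(x$temperature)))
  cat(sprintf("  mu_eff(U) = %.6g + %.6g * U^(%.6g - 1)  [mPa.s, U in 1/s]\n",
              x$mu0, x$k, x$n))
  invisible(x)
}

#' Ostwald-de Waele (power-law) parameters
#'
#' \deqn{\mu_{eff}(U) = k U^{\,n-1}}
#' The simplest power-law viscosity; unlike the Sisko model it diverges at
#' low shear (for n < 1) and vanishes at high shear.
#'
#' @param k Consistency index, mPa.s.s^(n-1); must be >= 0.
#' @param n Degree of non-Newtonian behaviour, dimensionless.
#' @return Object of class `power_law_params`.
#' @export
power_law_params <- function(k, n) {
  k <- as.numeric(k)[1]; n <- as.numeric(n)[1]
  if (!is.finite(k) || k < 0) stop("`k` must be finite and >= 0")
  if (!is.finite(n)) stop("`n` must be finite")
  structure(list(k = k, n = n), class = "power_law_params")
}

#' Evaluate the Sisko viscosity law
#'
#' @param params A [sisko_params] object.
#' @param shear_rate Shear rate(s) in 1/s; must be strictly positive (the
#'   power-law term diverges as U -> 0 when n < 1).
#' @return Effective viscosity in mPa.s (vectorized over `shear_rate`).
#' @examples
#' eval_sisko(embolic_sisko_params("squid12", 37), 10) # ~12.155 mPa.s
#' @export
eval_sisko <- function(params, shear_rate) {
  stopifnot(inherits(params, "sisko_params"))
  shear_rate <- as.numeric(shear_rate)
  if (length(shear_rate) == 0 || any(!is.finite(shear_rate)) ||
      any(shear_rate <= 0))
    stop("`shear_rate` must be finite and strictly positive")
  params$mu0 + params$k * shear_rate^(params$n - 1)
}

#' Evaluate the Ostwald-de Waele power law
#'
#' @param params A [power_law_params] object.
#' @param shear_rate Shear rate(s) in 1/s, strictly positive.
#' @return Effective viscosity in mPa.s.
#' @export
eval_power_law <- function(params, shear_rate) {
  stopifnot(inherits(params, "power_law_params"))
  shear_rate <- as.numeric(shear_rate)
  if (length(shear_rate) == 0 || any(!is.finite(shear_rate)) ||
      any(shear_rate <= 0))
    stop("`shear_rate` must be finite and strictly positive")
  params$k * shear_rate^(params$n - 1)
}

#' A rheometry flow curve
#'
#' One viscosity-curve test: effective viscosity measured over a sweep of
#' shear rates at a fixed temperature. Points are sorted by shear rate;
#' shear rates must be distinct and positive, viscosities positive, and at
#' least 3 points are required.
#'
#' @param shear_rates Shear rates, 1/s.
#' @param viscosities Effective viscosities, mPa.s; same length.
#' @param temperature Measurement temperature, degC.
#' @param polymer_label Free-text sample label.
#' @param mixed_tantalum Logical; whether the tantalum contrast powder was
#'   agitated into suspension before the test.
#' @return Object of class `rheometry_curve`.
#' @export
rheometry_curve <- function(shear_rates, viscosities, temperature = NA_real_,
                            polymer_label = "", mixed_tantalum = TRUE) {
  shear_rates <- as.numeric(shear_rates)
  viscosities <- as.numeric(viscosities)
  if (length(shear_rates) != length(viscosities))
    stop("`shear_rates` and `viscosities` must have equal length")
  if (length(shear_rates) < 3)
    stop("a flow curve needs at least 3 points")
  if (any(!is.finite(shear_rates)) || any(shear_rates <= 0))
    stop("all shear rates must be finite and > 0")
  if (any(!is.finite(viscosities)) || any(viscosities <= 0))
    stop("all viscosities must be finite and > 0")
  ord <- order(shear_rates)
  shear_rates <- shear_rates[ord]; viscosities <- viscosities[ord]
  if (any(diff(shear_rates) <= 0))
    stop("shear rates must be distinct (strictly increasing after sorting)")
  structure(list(shear_rates = shear_rates, viscosities = viscosities,
                 temperature = as.numeric(temperature)[1],
                 polymer_label = as.character(polymer_label)[1],
                 mixed_tantalum = isTRUE(mixed_tantalum)),
            class = "rheometry_curve")
}

#' @export
print.rheometry_curve <- function(x, ...) {
  lab <- if (nzchar(x$polymer_label)) x$polymer_label else "<unlabelled>"
  cat(sprintf(
    "Rheometry flow curve: %s at %s degC (%s tantalum), %d points, %.3g-%.3g 1/s\n",
    lab, format(x$temperature),
    if (x$mixed_tantalum) "mixed" else "unmixed",
    length(x$shear_rates), min(x$shear_rates), max(x$shear_rates)))
  invisible(x)
}

#' @export
as.data.frame.rheometry_curve <- function(x, ...) {
  data.frame(shear_rate_per_s = x$shear_rates,
             viscosity_mPas = x$viscosities,
             temperature_C = x$temperature,
             polymer = x$polymer_label,
             mixed_tantalum = x$mixed_tantalum)
}
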