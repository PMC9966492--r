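#' Temperature-dependent viscosity between two measured anchors
#'
#' The embolic agent is injected at room temperature (about 20 degC) and
#' warms to body temperature (37 degC) inside the catheter; its viscosity was
#' measured only at these two anchors. Between them the package interpolates
#' log-viscosity linearly in temperature (an Arrhenius-like form): the
#' simplest strictly positive interpolant that reproduces both anchor models
#' exactly. This is a modeling choice of the package, not a measured law.
#'
#' @param params_cold [sisko_params] at the cold anchor (e.g. 20 degC).
#' @param params_warm [sisko_params] at the warm anchor (e.g. 37 degC);
#'   must be at a strictly higher temperature.
#' @return Object of class `temperature_viscosity_law`.
#' @seealso [eval_temperature_interpolated()], [embolic_temperature_law()]
#' @export
temperature_viscosity_law <- function(params_cold, params_warm) {
  stopifnot(inherits(params_cold, "sisko_params"),
            inherits(params_warm, "sisko_params"))
  if (!is.finite(params_cold$temperature) || !is.finite(params_warm$temperature))
    stop("both anchor parameter sets need a finite temperature")
  if (params_cold$temperature >= params_warm$temperature)
    stop("`params_cold` must be at a lower temperature than `params_warm`")
  structure(list(params_cold = params_cold, params_warm = params_warm,
                 interpolation = "log-linear"),
            class = "temperature_viscosity_law")
}

#' @export
print.temperature_viscosity_law <- function(x, ...) {
  cat(sprintf(
    "Temperature-viscosity law (%s in T): anchors %g degC and %g degC\n",
    x$interpolation, x$params_cold$temperature, x$params_warm$temperature))
  invisible(x)
}

#' Viscosity at intermediate temperature and shear rate
#'
#' Evaluates both anchor Sisko models at the requested shear rate and
#' interpolates log-viscosity linearly in temperature. At the anchors the
#' anchor models are reproduced exactly. Temperatures within \[15, 45\] degC
#' outside the anchor interval are mild extrapolations and raise a warning;
#' beyond that range evaluation is refused.
#'
#' @param law A [temperature_viscosity_law].
#' @param temperature Temperature in degC, within \[15, 45\].
#' @param shear_rate Shear rate in 1/s, strictly positive.
#' @return Viscosity in mPa.s (vectorized over `temperature` or
#'   `shear_rate`).
#' @examples
#' law <- embolic_temperature_law("onyx18")
#' # geometric mean of the anchors at the midpoint temperature:
#' eval_temperature_interpolated(law, 28.5, 10)
#' @export
eval_temperature_interpolated <- function(law, temperature, shear_rate) {
  stopifnot(inherits(law, "temperature_viscosity_law"))
  temperature <- as.numeric(temperature)
  if (any(!is.finite(temperature)) ||
      any(temperature < 15) || any(temperature > 45))
    stop("`temperature` must lie within [15, 45] degC")
  t_cold <- law$params_cold$temperature
  t_warm <- law$params_warm$temperature
  if (any(temperature < t_cold) || any(temperature > t_warm))
    warning("extrapolating the viscosity law outside its [",
            t_cold, ", ", t_warm, "] degC anchors")
  mu_cold <- eval_sisko(law$params_cold, shear_rate)
  mu_warm <- eval_sisko(law$params_warm, shear_rate)
  w <- (temperature - t_cold) / (t_warm - t_cold)
  exp((1 - w) * log(mu_cold) + w * log(mu_warm))
}
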