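#' Configuration of the catheter warm-up model
#'
#' Lumped 1D plug-flow heat exchanger for the intracorporeal catheter
#' segment: the agent enters at room temperature and is warmed towards body
#' temperature through the catheter wall. Defaults reflect the delivery
#' scenario: 1 mm lumen, 0.2 mm wall, 1 m intracorporeal length, 0.6 mL/min,
#' 20 degC inlet, 37 degC body, DMSO thermal constants, and the laminar
#' fully-developed constant-wall-temperature Nusselt number 3.66.
#'
#' @param lumen_diameter m; > 0.
#' @param wall_thickness m; > 0.
#' @param length Intracorporeal catheter length, m; > 0.
#' @param inflow Volumetric rate, m^3/s; default 1e-8 (0.6 mL/min).
#' @param inlet_temperature degC; must be below `body_temperature`.
#' @param body_temperature degC.
#' @param conductivity Fluid thermal conductivity, W/m/K.
#' @param specific_heat J/kg/K.
#' @param density kg/m^3.
#' @param nusselt Dimensionless film Nusselt number, default 3.66.
#' @param wall_conductivity Catheter wall conductivity, W/m/K (used only
#'   when `include_wall_resistance`).
#' @param include_wall_resistance Logical; add the cylindrical wall
#'   conduction resistance in series with the film. Default `FALSE`.
#' @return Object of class `thermal_config`.
#' @export
thermal_config <- function(lumen_diameter = 1e-3, wall_thickness = 0.2e-3,
                           length = 1, inflow = 1e-8,
                           inlet_temperature = 20, body_temperature = 37,
                           conductivity = dmso_properties()$conductivity,
                           specific_heat = dmso_properties()$specific_heat,
                           density = dmso_properties()$density,
                           nusselt = 3.66, wall_conductivity = 0.2,
                           include_wall_resistance = FALSE) {
  num <- c(lumen_diameter = lumen_diameter, wall_thickness = wall_thickness,
           length = length, inflow = inflow, conductivity = conductivity,
           specific_heat = specific_heat, density = density,
           nusselt = nusselt, wall_conductivity = wall_conductivity)
  for (nm in names(num))
    if (!is.finite(num[[nm]]) || num[[nm]] <= 0)
      stop("`", nm, "` must be finite and > 0")
  if (!is.finite(inlet_temperature) || !is.finite(body_temperature))
    stop("temperatures must be finite")
  if (inlet_temperature > body_temperature)
    stop("warming scenario requires `inlet_temperature` <= `body_temperature`")
  structure(c(as.list(num),
              list(inlet_temperature = inlet_temperature,
                   body_temperature = body_temperature,
                   include_wall_resistance = isTRUE(include_wall_resistance))),
            class = "thermal_config")
}

#' Inner-surface heat transfer coefficient
#'
#' Convective film coefficient `h = Nu k / d`; with
#' `include_wall_resistance` the cylindrical wall conduction resistance
#' (referred to the inner surface) is composed in series:
#' `1/U = 1/h + d ln((d + 2t)/d) / (2 k_wall)`. As the wall conductivity
#' grows the composed value tends to the bare film value.
#'
#' @param config A [thermal_config].
#' @return Heat transfer coefficient, W/m^2/K.
#' @examples
#' heat_transfer_coefficient(thermal_config()) # 3.66 * 0.2 / 1e-3 = 732
#' @export
heat_transfer_coefficient <- function(config) {
  stopifnot(inherits(config, "thermal_config"))
  h <- config$nusselt * config$conductivity / config$lumen_diameter
  if (config$include_wall_resistance) {
    d <- config$lumen_diameter
    r_wall <- d * log((d + 2 * config$wall_thickness) / d) /
      (2 * config$wall_conductivity)
    h <- 1 / (1 / h + r_wall)
  }
  h
}

# exponential decay length of the axial temperature deficit, m
thermal_decay_length <- function(config) {
  h <- heat_transfer_coefficient(config)
  config$density * config$specific_heat * config$inflow /
    (h * pi * config$lumen_diameter)
}

#' Axial temperature profile along the catheter
#'
#' Closed-form solution of the lumped plug-flow energy balance with constant
#' wall temperature:
#' \deqn{T(x) = T_{body} - (T_{body} - T_{in}) e^{-x/x^*}, \qquad
#'       x^* = \frac{\rho c_p Q}{h \pi d}}
#' evaluated exactly on a uniform axial grid (no time stepping). With the
#' defaults the decay length is about 9.4 mm, so over a 1 m neurosurgical
#' catheter the agent reaches body temperature with margin to spare.
#'
#' @param config A [thermal_config].
#' @param n_points Number of grid points, >= 2; default 100.
#' @return Object of class `thermal_profile` with `x_m`, `temperature_C`,
#'   `viscosity_mPas` (`NA` until composed with a viscosity law, see
#'   [viscosity_profile()]), `decay_length_m` and `warmup_length_95_m`.
#' @export
axial_temperature_profile <- function(config, n_points = 100L) {
  stopifnot(inherits(config, "thermal_config"))
  n_points <- as.integer(n_points)
  if (n_points < 2) stop("`n_points` must be >= 2")
  x <- seq(0, config$length, length.out = n_points)
  xs <- thermal_decay_length(config)
  temp <- config$body_temperature -
    (config$body_temperature - config$inlet_temperature) * exp(-x / xs)
  structure(list(x_m = x, temperature_C = temp,
                 viscosity_mPas = rep(NA_real_, n_points),
                 decay_length_m = xs,
                 warmup_length_95_m = -xs * log(1 - 0.95),
                 total_pressure_drop_Pa = NA_real_,
                 config = config),
            class = "thermal_profile")
}

#' Warm-up length for a given temperature recovery fraction
#'
#' Length at which the temperature deficit `(T_body - T(x))` has shrunk to
#' `(1 - fraction)` of its inlet value: `-x* log(1 - fraction)`. With the
#' defaults the 95 percent warm-up length is about 28 mm -- far below a 1 m
#' neurosurgical catheter, but comparable to the centimeters of
#' intracorporeal catheter in infant or short-access procedures, where the
#' agent may reach the blood incompletely warmed.
#'
#' @param config A [thermal_config].
#' @param fraction Recovery fraction in (0, 1).
#' @return Length, m.
#' @export
warmup_length <- function(config, fraction) {
  stopifnot(inherits(config, "thermal_config"))
  if (!is.numeric(fraction) || any(!is.finite(fraction)) ||
      any(fraction <= 0) || any(fraction >= 1))
    stop("`fraction` must lie strictly within (0, 1)")
  -thermal_decay_length(config) * log(1 - fraction)
}

#' Axial viscosity profile and heated-catheter pressure drop
#'
#' Composes the axial temperature profile with the temperature-interpolated
#' viscosity law, evaluated at the catheter wall shear rate (constant along
#' the catheter, since diameter and flow are constant), and integrates the
#' Poiseuille pressure gradient `32 mu(x) c / d^2` over the grid by the
#' trapezoidal rule.
#'
#' @param config A [thermal_config].
#' @param law A [temperature_viscosity_law]; its anchors must cover the
#'   inlet and body temperatures.
#' @param n_points Axial grid points; default 200.
#' @return A `thermal_profile` with the viscosity column filled and
#'   `total_pressure_drop_Pa` set.
#' @export
viscosity_profile <- function(config, law, n_points = 200L) {
  stopifnot(inherits(config, "thermal_config"),
            inherits(law, "temperature_viscosity_law"))
  prof <- axial_temperature_profile(config, n_points)
  gamma <- wall_shear_rate(config$inflow, config$lumen_diameter)
  prof$viscosity_mPas <- eval_temperature_interpolated(
    law, prof$temperature_C, gamma)
  c_mean <- mean_velocity(config$inflow, config$lumen_diameter)
  grad <- 32 * (prof$viscosity_mPas * 1e-3) * c_mean / config$lumen_diameter^2
  dx <- diff(prof$x_m)
  prof$total_pressure_drop_Pa <-
    sum(dx * (grad[-1] + grad[-length(grad)]) / 2)
  prof
}

#' @export
print.thermal_profile <- function(x, ...) {
  n <- length(x$x_m)
  cat(sprintf(
    "Catheter thermal profile: %d points over %.3g m, decay length %.3g mm\n",
    n, max(x$x_m), 1e3 * x$decay_length_m))
  cat(sprintf("  inlet %.2f degC -> outlet %.4f degC (body %.2f degC)\n",
              x$temperature_C[1], x$temperature_C[n],
              x$config$body_temperature))
  if (!is.na(x$total_pressure_drop_Pa))
    cat(sprintf("  viscosity %.4g -> %.4g mPa.s; integrated pressure drop %.4g Pa\n",
                x$viscosity_mPas[1], x$viscosity_mPas[n],
                x$total_pressure_drop_Pa))
  invisible(x)
}

#' @export
as.data.frame.thermal_profile <- function(x, ...) {
  data.frame(x_m = x$x_m, temperature_C = x$temperature_C,
             viscosity_mPas = x$viscosity_mPas)
}
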