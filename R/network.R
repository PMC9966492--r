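#' A vessel (or catheter) segment
#'
#' A straight circular tube, possibly replicated as `n_parallel` identical
#' parallel tubes (the racemose compartment of an AVM nidus is modeled as a
#' bundle of identical small vessels).
#'
#' @param label Segment name.
#' @param length Tube length, m; > 0.
#' @param diameter Inner diameter, m; > 0.
#' @param n_parallel Count of identical parallel tubes, >= 1.
#' @return Object of class `vessel_segment`.
#' @export
vessel_segment <- function(label, length, diameter, n_parallel = 1L) {
  length <- as.numeric(length)[1]; diameter <- as.numeric(diameter)[1]
  n_parallel <- as.integer(n_parallel)[1]
  if (!is.finite(length) || length <= 0) stop("`length` must be > 0")
  if (!is.finite(diameter) || diameter <= 0) stop("`diameter` must be > 0")
  if (is.na(n_parallel) || n_parallel < 1) stop("`n_parallel` must be >= 1")
  structure(list(label = as.character(label)[1], length = length,
                 diameter = diameter, n_parallel = n_parallel),
            class = "vessel_segment")
}

#' Catheter + AVM network geometry
#'
#' The reduced-order embolization geometry: the delivery catheter feeds a
#' feeding artery, which splits into the racemose bundle (identical small
#' parallel vessels) hydraulically in parallel with an optional fistula (a
#' single large direct shunt, typically 4 mm), re-collecting into a draining
#' vessel. Series segments carry the full inflow; the parallel block splits
#' it so both branches see the same pressure drop.
#'
#' @param catheter,feeder,racemose,drainer [vessel_segment] objects in series.
#' @param fistula Optional [vessel_segment] in parallel with the racemose
#'   bundle, or `NULL`.
#' @param inflow Volumetric delivery rate, m^3/s; default 0.6 mL/min
#'   (1e-8 m^3/s), the typical injection rate.
#' @param fluid_density kg/m^3; default 1100 (DMSO-dominated agent).
#' @param viscosity_law A [sisko_params] (used as-is) or a
#'   [temperature_viscosity_law] evaluated at `temperature`.
#' @param temperature Working temperature, degC (used only with a
#'   temperature law); default 37.
#' @return Object of class `avm_network`.
#' @seealso [default_avm_network()], [solve_network()]
#' @export
avm_network <- function(catheter, feeder, racemose, drainer, fistula = NULL,
                        inflow = 1e-8, fluid_density = 1100,
                        viscosity_law = NULL, temperature = 37) {
  for (s in list(catheter, feeder, racemose, drainer))
    stopifnot(inherits(s, "vessel_segment"))
  if (!is.null(fistula)) stopifnot(inherits(fistula, "vessel_segment"))
  if (!is.finite(inflow) || inflow <= 0) stop("`inflow` must be > 0")
  if (!is.finite(fluid_density) || fluid_density <= 0)
    stop("`fluid_density` must be > 0")
  if (is.null(viscosity_law) ||
      !(inherits(viscosity_law, "sisko_params") ||
        inherits(viscosity_law, "temperature_viscosity_law")))
    stop("`viscosity_law` must be sisko_params or temperature_viscosity_law")
  structure(list(catheter = catheter, feeder = feeder, racemose = racemose,
                 fistula = fistula, drainer = drainer, inflow = inflow,
                 fluid_density = fluid_density, viscosity_law = viscosity_law,
                 temperature = as.numeric(temperature)[1]),
            class = "avm_network")
}

#' Default AVM network
#'
#' Plausible AVM-scale defaults: 1 m x 2 mm catheter (6 Fr lumen over a
#' femoral-to-cranial access length), 20 mm x 3 mm feeder, racemose bundle of
#' 10 tubes of 10 mm x 1 mm, optional 10 mm x 4 mm fistula, 20 mm x 3 mm
#' drainer, 0.6 mL/min inflow.
#'
#' @param viscosity_law As in [avm_network()].
#' @param racemose_diameter Racemose vessel diameter, m; default 1e-3.
#' @param with_fistula Logical; include the 4 mm fistula. Default `FALSE`.
#' @param ... Passed on to [avm_network()].
#' @return An `avm_network`.
#' @export
default_avm_network <- function(viscosity_law, racemose_diameter = 1e-3,
                                with_fistula = FALSE, ...) {
  avm_network(
    catheter = vessel_segment("catheter", 1.0, 2e-3),
    feeder   = vessel_segment("feeder", 20e-3, 3e-3),
    racemose = vessel_segment("racemose", 10e-3, racemose_diameter,
                              n_parallel = 10L),
    fistula  = if (with_fistula) vessel_segment("fistula", 10e-3, 4e-3),
    drainer  = vessel_segment("drainer", 20e-3, 3e-3),
    viscosity_law = viscosity_law, ...)
}

#' Mean velocity in a circular tube
#'
#' @param Q Volumetric flow, m^3/s; > 0.
#' @param d Inner diameter, m; > 0.
#' @return Mean (bulk) velocity, m/s. At the typical delivery rate of
#'   0.6 mL/min through a 2 mm (6 Fr) lumen this is about 3 mm/s.
#' @export
mean_velocity <- function(Q, d) {
  check_positive(Q = Q, d = d)
  Q / (pi * d^2 / 4)
}

#' Poiseuille wall shear rate in a circular tube
#'
#' For a parabolic (Poiseuille) profile the shear rate at the wall is
#' `8 u_mean / d`, equivalently `32 Q / (pi d^3)`. At 0.6 mL/min through a
#' 2 mm lumen this is about 13 1/s -- the order-10 1/s catheter shear rate at
#' which temperature, rather than shear, governs the agent's viscosity.
#'
#' @inheritParams mean_velocity
#' @return Wall shear rate, 1/s.
#' @export
wall_shear_rate <- function(Q, d) {
  check_positive(Q = Q, d = d)
  32 * Q / (pi * d^3)
}

#' Poiseuille pressure drop in a circular tube
#'
#' \deqn{\delta p = 32 \mu l c / d^2}
#'
#' @param mu Dynamic viscosity, Pa.s; > 0.
#' @param l Tube length, m; > 0.
#' @param c Mean velocity, m/s; > 0.
#' @param d Inner diameter, m; > 0.
#' @return Pressure drop, Pa.
#' @export
poiseuille_pressure_drop <- function(mu, l, c, d) {
  check_positive(mu = mu, l = l, c = c, d = d)
  32 * mu * l * c / d^2
}

#' Darcy-Weisbach head loss
#'
#' \deqn{h = \lambda \frac{l}{d} \frac{c^2}{2g}}
#' In the laminar regime `lambda = 64/Re` and `rho g h` reduces exactly to
#' the Poiseuille pressure drop.
#'
#' @param lambda_f Darcy friction factor, dimensionless; > 0.
#' @param l Tube length, m.
#' @param d Inner diameter, m.
#' @param c Mean velocity, m/s.
#' @param g Local gravitational acceleration, m/s^2; default 9.80665.
#' @return Head loss in meters of fluid column.
#' @export
darcy_weisbach_head_loss <- function(lambda_f, l, d, c, g = 9.80665) {
  check_positive(lambda_f = lambda_f, l = l, d = d, c = c, g = g)
  lambda_f * (l / d) * c^2 / (2 * g)
}

#' Reynolds number
#'
#' `Re = rho u L / mu` with the tube diameter as characteristic length.
#' Embolic flow is deep in the laminar regime: for Squid-12 at body
#' temperature in the catheter, Re is about 0.6.
#'
#' @param rho Density, kg/m^3.
#' @param u Velocity, m/s.
#' @param L Characteristic (hydraulic) length, m.
#' @param mu Dynamic viscosity, Pa.s.
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(rho, u, L, mu) {
  check_positive(rho = rho, u = u, L = L, mu = mu)
  rho * u * L / mu
}

#' Wall shear stress
#'
#' `tau = mu * gamma_wall`, reported in dyne/cm^2 (1 Pa = 10 dyne/cm^2), the
#' unit used for vascular wall shear stress.
#'
#' @param mu Dynamic viscosity, Pa.s; >= 0.
#' @param gamma_wall Wall shear rate, 1/s; >= 0.
#' @return Wall shear stress, dyne/cm^2.
#' @export
wall_shear_stress <- function(mu, gamma_wall) {
  if (any(!is.finite(mu)) || any(mu < 0)) stop("`mu` must be >= 0")
  if (any(!is.finite(gamma_wall)) || any(gamma_wall < 0))
    stop("`gamma_wall` must be >= 0")
  10 * mu * gamma_wall
}

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (any(!is.finite(v)) || any(v <= 0))
      stop("`", nm, "` must be finite and strictly positive")
  }
  invisible(TRUE)
}

# Viscosity in mPa.s as a function of shear rate, per the network's law.
# The shear rate is clamped to the measured flow-curve window (0.1-100 1/s)
# before evaluation: the Sisko constants are calibrated there, and power-law
# extrapolation below it (where n < 0 makes the implied stress-shear law
# non-monotone) would let branch resistances diverge at small flows.
# Beyond the window the nearest measured viscosity is carried constant.
shear_clamp <- c(0.1, 100)

network_viscosity_fun <- function(net) {
  law <- net$viscosity_law
  base <- if (inherits(law, "sisko_params")) {
    function(U) eval_sisko(law, U)
  } else {
    function(U) eval_temperature_interpolated(law, net$temperature, U)
  }
  function(U) base(pmin(pmax(U, shear_clamp[1]), shear_clamp[2]))
}

# pressure drop (Pa) of one tube at per-tube flow q, viscosity from the
# tube's own wall shear rate
tube_pressure_drop <- function(q, d, l, visc) {
  mu <- visc(wall_shear_rate(q, d)) * 1e-3
  128 * mu * l * q / (pi * d^4)
}

# split total flow Q between N identical racemose tubes (per-tube flow q_r)
# and one fistula so both branches see the same pressure drop; the
# shear-dependent viscosities are evaluated inside the residual, so the
# returned split is exactly pressure-balanced for the converged viscosities.
solve_parallel_split <- function(Q, rac, fis, visc) {
  N <- rac$n_parallel
  g <- function(q_r)
    tube_pressure_drop(q_r, rac$diameter, rac$length, visc) -
    tube_pressure_drop(Q - N * q_r, fis$diameter, fis$length, visc)
  lo <- Q / N * 1e-9; hi <- Q / N * (1 - 1e-9)
  if (sign(g(lo)) == sign(g(hi)))
    stop("parallel flow split has no sign change on the bracket")
  root <- stats::uniroot(g, c(lo, hi), tol = Q / N * 1e-14, maxiter = 1000L)
  q_r <- root$root
  list(q_rac = q_r, q_fis = Q - N * q_r, iterations = root$iter)
}

#' Solve steady non-Newtonian flow through the network
#'
#' Reduced-order (1D) resistance-network solution: each tube obeys the
#' Poiseuille law with its viscosity evaluated at its own wall shear rate
#' (the approximate-shear-rate closure; the exact shear-dependent velocity
#' profile is deliberately not resolved). Since the shear rate depends on
#' the flow split and the split on the viscosities, the solver iterates the
#' fixed point viscosity -> resistance -> flow split -> shear rate ->
#' viscosity until the largest relative viscosity change falls below `tol`.
#' A Newtonian law converges in the first iteration; oscillation triggers
#' 0.5 damping. Identical parallel racemose tubes are treated symmetrically
#' by construction, so mass conservation at the junctions holds to rounding.
#'
#' @param net An [avm_network].
#' @param tol Relative viscosity-change tolerance, default 1e-8.
#' @param max_iter Iteration cap, default 200; non-convergence is returned
#'   (flagged, with the last iterate and defect norms), not thrown.
#' @return Object of class `network_solution`: `segments` (a data.frame with
#'   per-segment per-tube flow, mean velocity, wall shear rate, viscosity in
#'   mPa.s, pressure drop, wall shear stress in dyne/cm^2, and Reynolds
#'   number), `total_pressure_drop_Pa`, `iterations`, `converged`,
#'   `mass_defect` and `parallel_pressure_defect` (relative).
#' @export
solve_network <- function(net, tol = 1e-8, max_iter = 200L) {
  stopifnot(inherits(net, "avm_network"))
  visc <- network_viscosity_fun(net)
  segs <- list(net$catheter, net$feeder, net$racemose)
  if (!is.null(net$fistula)) segs <- c(segs, list(net$fistula))
  segs <- c(segs, list(net$drainer))
  labels <- vapply(segs, `[[`, character(1), "label")
  len <- vapply(segs, `[[`, numeric(1), "length")
  dia <- vapply(segs, `[[`, numeric(1), "diameter")
  npar <- vapply(segs, `[[`, numeric(1), "n_parallel")
  has_fistula <- !is.null(net$fistula)
  i_rac <- 3L; i_fis <- if (has_fistula) 4L else NA_integer_
  parallel <- seq_along(segs) %in% c(i_rac, i_fis)
  Q <- net$inflow

  flows <- function() {
    q <- Q / npar                      # series segments carry everything
    if (has_fistula) {
      split <- solve_parallel_split(Q, net$racemose, net$fistula, visc)
      q[i_rac] <- split$q_rac
      q[i_fis] <- split$q_fis
    }
    q
  }

  mu <- visc(wall_shear_rate(Q / npar, dia))
  iter <- 0L; converged <- FALSE
  split_err <- NULL
  repeat {
    iter <- iter + 1L
    q <- tryCatch(flows(), error = function(e) e)
    if (inherits(q, "error")) { split_err <- q; break }
    gamma <- wall_shear_rate(q, dia)
    mu_new <- visc(gamma)
    rel <- max(abs(mu_new - mu) / mu)
    mu <- mu_new
    if (rel < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!is.null(split_err)) {
    warning("network solve failed: ", conditionMessage(split_err))
    q <- Q / npar
    gamma <- wall_shear_rate(q, dia)
  }
  gamma <- wall_shear_rate(q, dia)
  vel <- mean_velocity(q, dia)
  dp <- poiseuille_pressure_drop(mu * 1e-3, len, vel, dia)
  wss <- wall_shear_stress(mu * 1e-3, gamma)
  re <- reynolds_number(net$fluid_density, vel, dia, mu * 1e-3)

  mass_defect <- abs(sum(q[parallel] * npar[parallel]) - Q) / Q
  if (!has_fistula) mass_defect <- abs(q[i_rac] * npar[i_rac] - Q) / Q
  parallel_defect <- if (has_fistula) {
    abs(dp[i_rac] - dp[i_fis]) / max(dp[i_rac], dp[i_fis])
  } else 0
  total_dp <- sum(dp[!parallel]) + dp[i_rac]

  structure(list(
    segments = data.frame(
      label = labels, n_parallel = as.integer(npar),
      flow_m3_s = q, velocity_m_s = vel, shear_rate_per_s = gamma,
      viscosity_mPas = mu, pressure_drop_Pa = dp, wss_dyne_cm2 = wss,
      reynolds = re, stringsAsFactors = FALSE),
    total_pressure_drop_Pa = total_dp,
    iterations = iter, converged = converged,
    mass_defect = mass_defect,
    parallel_pressure_defect = parallel_defect),
    class = "network_solution")
}

#' @export
print.network_solution <- function(x, ...) {
  cat(sprintf(
    "1D network solution: total pressure drop %.4g Pa (%s, %d iteration%s)\n",
    x$total_pressure_drop_Pa,
    if (x$converged) "converged" else "NOT converged",
    x$iterations, if (x$iterations == 1) "" else "s"))
  print(x$segments, digits = 4)
  invisible(x)
}

#' Sweep racemose vessel diameter, with and without fistula
#'
#' Re-solves the network over a list of racemose diameters, optionally in
#' both the fistula and no-fistula configurations, and summarizes each case
#' by the quantities reported for AVM embolization studies: racemose
#' pressure drop, racemose wall shear stress, peak velocity and peak
#' Reynolds number. Solver failures are flagged per row and the sweep
#' continues. Rows are ordered by diameter, then fistula status.
#'
#' @param net_template An [avm_network] used for everything except the
#'   racemose diameter (its fistula, if absent, defaults to 10 mm x 4 mm for
#'   the with-fistula cases).
#' @param diameters Racemose diameters, m; each within (0.1, 5) mm.
#' @param with_and_without_fistula If `TRUE` (default) each diameter is
#'   solved both with and without the fistula; otherwise only in the
#'   template's own configuration.
#' @return data.frame with columns `diameter_mm`, `fistula`, `polymer`,
#'   `pressure_Pa`, `wss_dyne_cm2`, `max_velocity_m_s`, `reynolds`,
#'   `iterations`, `converged`.
#' @export
sweep_diameters <- function(net_template, diameters,
                            with_and_without_fistula = TRUE) {
  stopifnot(inherits(net_template, "avm_network"))
  diameters <- as.numeric(diameters)
  if (length(diameters) == 0) {
    return(data.frame(diameter_mm = numeric(0), fistula = logical(0),
                      polymer = character(0), pressure_Pa = numeric(0),
                      wss_dyne_cm2 = numeric(0), max_velocity_m_s = numeric(0),
                      reynolds = numeric(0), iterations = integer(0),
                      converged = logical(0), stringsAsFactors = FALSE))
  }
  if (any(diameters <= 0.1e-3) || any(diameters >= 5e-3))
    stop("`diameters` must lie within (0.1, 5) mm")
  fistula_seg <- if (!is.null(net_template$fistula)) net_template$fistula
    else vessel_segment("fistula", 10e-3, 4e-3)
  law <- net_template$viscosity_law
  polymer <- if (inherits(law, "sisko_params")) law$polymer_label
    else law$params_warm$polymer_label
  fist_cases <- if (with_and_without_fistula) c(FALSE, TRUE)
    else !is.null(net_template$fistula)

  rows <- list()
  for (d in sort(diameters)) for (fist in fist_cases) {
    net <- net_template
    net$racemose$diameter <- d
    net$fistula <- if (fist) fistula_seg else NULL
    sol <- solve_network(net)
    rac <- sol$segments[sol$segments$label == net$racemose$label, ]
    rows[[length(rows) + 1L]] <- data.frame(
      diameter_mm = d * 1e3, fistula = fist, polymer = polymer,
      pressure_Pa = rac$pressure_drop_Pa, wss_dyne_cm2 = rac$wss_dyne_cm2,
      max_velocity_m_s = max(sol$segments$velocity_m_s),
      reynolds = max(sol$segments$reynolds),
      iterations = sol$iterations, converged = sol$converged,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
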