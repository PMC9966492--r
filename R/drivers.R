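#' Read a structured run configuration
#'
#' Configurations are plain YAML with per-command sections (`generate`,
#' `sweep`, `thermal`). Physical defaults -- the published Sisko constants,
#' DMSO thermal properties and the default geometries -- are built into the
#' package, so a config only states deviations from them.
#'
#' @param path YAML file path.
#' @return Named list of configuration sections.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

resolve_polymer <- function(polymer) {
  p <- tolower(gsub("[^a-z0-9]", "", tolower(polymer)))
  if (p %in% c("onyx18", "onyx")) "onyx18"
  else if (p %in% c("squid12", "squid")) "squid12"
  else stop("unknown polymer '", polymer, "' (use onyx18 or squid12)")
}

#' Run a diameter sweep from a configuration
#'
#' Driver for the network sweep: builds the default network for each
#' requested polymer (Sisko constants at the working temperature), sweeps
#' the racemose diameters with and without fistula, and returns (optionally
#' writes) the combined deterministic table with header
#' `diameter_mm,fistula,polymer,pressure_Pa,wss_dyne_cm2,max_velocity_m_s,reynolds,iterations,converged`.
#'
#' @param config List with optional entries `polymers` (default both),
#'   `diameters_mm` (default the nine vessel diameters 0.5-2 mm),
#'   `temperature` (default 37), `inflow_m3_s`, `density_kg_m3`.
#' @param out Optional CSV path.
#' @return data.frame of sweep rows, diameters nested within polymer.
#' @export
run_sweep <- function(config = list(), out = NULL) {
  polymers <- vapply(config$polymers %||% c("onyx18", "squid12"),
                     resolve_polymer, character(1))
  diam_mm <- config$diameters_mm %||% c(0.5, 0.75, 0.9, 1, 1.25, 1.5, 1.75, 1.9, 2)
  temperature <- config$temperature %||% 37
  tabs <- lapply(polymers, function(p) {
    net <- default_avm_network(
      embolic_sisko_params(p, temperature),
      inflow = config$inflow_m3_s %||% 1e-8,
      fluid_density = config$density_kg_m3 %||% 1100)
    sweep_diameters(net, diam_mm * 1e-3, with_and_without_fistula = TRUE)
  })
  res <- do.call(rbind, tabs)
  rownames(res) <- NULL
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE, quote = FALSE)
  res
}

#' Run the catheter warm-up model from a configuration
#'
#' Driver for the thermal profile: builds the thermal configuration (all
#' entries optional, defaulting to the 1 mm / 0.6 mL/min / DMSO scenario),
#' composes it with the requested polymer's temperature-viscosity law and
#' returns (optionally writes) the axial profile CSV with header
#' `x_m,temperature_C,viscosity_mPas`.
#'
#' @param config List with optional entries `polymer` (default squid12),
#'   `lumen_diameter_m`, `length_m`, `inflow_m3_s`, `inlet_temperature_C`,
#'   `body_temperature_C`, `n_points`.
#' @param out Optional CSV path.
#' @return The `thermal_profile` object, invisibly when written.
#' @export
run_thermal <- function(config = list(), out = NULL) {
  polymer <- resolve_polymer(config$polymer %||% "squid12")
  tc <- thermal_config(
    lumen_diameter = config$lumen_diameter_m %||% 1e-3,
    length = config$length_m %||% 1,
    inflow = config$inflow_m3_s %||% 1e-8,
    inlet_temperature = config$inlet_temperature_C %||% 20,
    body_temperature = config$body_temperature_C %||% 37)
  prof <- viscosity_profile(tc, embolic_temperature_law(polymer),
                            n_points = config$n_points %||% 200L)
  if (!is.null(out)) {
    utils::write.csv(as.data.frame(prof), out, row.names = FALSE,
                     quote = FALSE)
    return(invisible(prof))
  }
  prof
}

#' Generate a synthetic rheometry dataset from a configuration
#'
#' Driver for the generator: one curve per entry of `config$curves`, each
#' with optional `polymer`, `temperature`, `noise_sd`, `bump_amplitude`,
#' `bump_center`, `bump_width`, `n_points`, `seed`, `mixed_tantalum`.
#' Missing `curves` means the four published (polymer x temperature)
#' combinations with the default noise.
#'
#' @param config List as above; a global `seed` offsets per-curve seeds.
#' @param out Optional flow-curve CSV path.
#' @return List of [rheometry_curve] objects.
#' @export
run_generate <- function(config = list(), out = NULL) {
  seed0 <- config$seed %||% 1L
  specs <- config$curves %||% {
    grid <- expand.grid(polymer = c("onyx18", "squid12"),
                        temperature = c(20, 37), stringsAsFactors = FALSE)
    lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, ]))
  }
  cfgs <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    base <- embolic_sisko_params(resolve_polymer(s$polymer %||% "squid12"),
                                 s$temperature %||% 37)
    if (isFALSE(s$mixed_tantalum %||% TRUE))
      base <- unmixed_tantalum_params(base)
    synthetic_rheometry_config(
      base, n_points = s$n_points %||% 30,
      noise_sd = s$noise_sd %||% 0.05,
      bump_amplitude = s$bump_amplitude %||% 0,
      bump_center = s$bump_center %||% 1,
      bump_width = s$bump_width %||% 0.15,
      seed = as.integer(seed0) + i - 1L,
      mixed_tantalum = !isFALSE(s$mixed_tantalum %||% TRUE))
  })
  generate_dataset(cfgs, file = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
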