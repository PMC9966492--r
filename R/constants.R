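#' Published Sisko constants for the studied embolic agents
#'
#' Empirical Sisko-model constants for Onyx-18 and Squid-12 fitted to
#' cone-plate rheometry flow curves at laboratory (20 degC) and physiological
#' (37 degC) temperature. `mu0` and `k` are interpreted in mPa.s (cP): the
#' high-shear plateau viscosities (about 18 cP for Onyx-18, about 12 cP for
#' Squid-12 at 37 degC) then match the products' nominal centipoise
#' designations. The flow index `n` is taken as printed, including the small
#' negative values at 20 degC.
#'
#' @param polymer `"onyx18"` or `"squid12"`.
#' @param temperature 20 or 37 (degC); the two measured anchors.
#' @return A [sisko_params] object.
#' @examples
#' eval_sisko(embolic_sisko_params("onyx18", 37), 1) # 21.18686 mPa.s
#' @export
embolic_sisko_params <- function(polymer = c("onyx18", "squid12"),
                                 temperature = c(20, 37)) {
  polymer <- match.arg(polymer)
  temperature <- as.numeric(match.arg(as.character(temperature[1]), c("20", "37")))
  tab <- list(
    onyx18  = list(`20` = c(31.6187, 1.80968, -0.004368),
                   `37` = c(18.0138, 3.17306,  0.271126)),
    squid12 = list(`20` = c(19.4711, 2.97360, -0.033290),
                   `37` = c(12.1248, 1.10875, -0.558600))
  )
  p <- tab[[polymer]][[as.character(temperature)]]
  label <- c(onyx18 = "Onyx-18", squid12 = "Squid-12")[[polymer]]
  sisko_params(mu0 = p[1], k = p[2], n = p[3],
               temperature = temperature, polymer_label = label)
}

#' Temperature-viscosity law between the two measured anchors
#'
#' Convenience wrapper building a [temperature_viscosity_law] from the
#' published 20 degC and 37 degC Sisko constants of one polymer.
#'
#' @inheritParams embolic_sisko_params
#' @return A `temperature_viscosity_law` object.
#' @export
embolic_temperature_law <- function(polymer = c("onyx18", "squid12")) {
  polymer <- match.arg(polymer)
  temperature_viscosity_law(embolic_sisko_params(polymer, 20),
                            embolic_sisko_params(polymer, 37))
}

#' Thermophysical constants of the DMSO-dominated embolic liquid
#'
#' More than 90 percent of the liquid phase is dimethyl sulfoxide, so the
#' carrier solvent's constants are used for the heat-transfer model:
#' thermal conductivity 0.2 W/m/K and specific heat 0.47 cal/g/degC
#' (1966.48 J/kg/K with 1 cal = 4.184 J). The density default of
#' 1100 kg/m^3 is a DMSO-dominated estimate, configurable because tantalum
#' loading raises it.
#'
#' @return Named list with `conductivity` (W/m/K), `specific_heat` (J/kg/K)
#'   and `density` (kg/m^3).
#' @export
dmso_properties <- function() {
  list(conductivity = 0.2,
       specific_heat = 0.47 * 4.184 * 1000,
       density = 1100)
}
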