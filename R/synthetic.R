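#' Configuration of the synthetic rheometry generator
#'
#' The generator emulates cone-plate viscosity-curve tests of the embolic
#' agents: a Sisko base law sampled on a log-spaced shear grid, an optional
#' localized dip near 1 1/s (the nonmonotonicity zone, about 30 percent deep
#' when enabled), and multiplicative lognormal noise (viscosity is positive
#' and spans decades, so scatter is naturally relative).
#'
#' The generated viscosity is
#' \deqn{\mu(U) = S(U)\,\bigl(1 - A e^{-(\log_{10}U - \log_{10}c)^2 / 2\sigma^2}\bigr)\,\varepsilon}
#' with \eqn{S} the Sisko base law, dip amplitude \eqn{A}, center \eqn{c}
#' (1/s), width \eqn{\sigma} in decades, and \eqn{\varepsilon} lognormal with
#' median 1.
#'
#' @param base_params [sisko_params] of the base law.
#' @param n_points Number of grid points (>= 3), default 30.
#' @param shear_range Length-2 shear interval in 1/s, log-spaced; default
#'   `c(0.1, 100)` (the plotted range of the flow-curve figures).
#' @param noise_sd Lognormal sigma of the multiplicative noise, default 0.05
#'   (a stand-in for unpublished replicate scatter).
#' @param bump_amplitude Fractional dip depth in \[0, 1); default 0 (off).
#' @param bump_center Dip center, 1/s; default 1.
#' @param bump_width Dip width in decades of shear rate; default 0.15.
#' @param seed Integer seed; generation is reproducible per configuration.
#' @param mixed_tantalum Logical label forwarded to the curve.
#' @return Object of class `synthetic_rheometry_config`.
#' @seealso [generate_curve()], [generate_dataset()]
#' @export
synthetic_rheometry_config <- function(base_params, n_points = 30,
                                       shear_range = c(0.1, 100),
                                       noise_sd = 0.05, bump_amplitude = 0,
                                       bump_center = 1, bump_width = 0.15,
                                       seed = 1L, mixed_tantalum = TRUE) {
  stopifnot(inherits(base_params, "sisko_params"))
  n_points <- as.integer(n_points)
  if (n_points < 3) stop("`n_points` must be >= 3")
  if (length(shear_range) != 2 || any(shear_range <= 0) ||
      shear_range[1] >= shear_range[2])
    stop("`shear_range` must be an increasing positive interval")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (!is.finite(bump_amplitude) || bump_amplitude < 0 || bump_amplitude >= 1)
    stop("`bump_amplitude` must lie in [0, 1)")
  if (!is.finite(bump_center) || bump_center <= 0)
    stop("`bump_center` must be > 0")
  if (!is.finite(bump_width) || bump_width <= 0)
    stop("`bump_width` must be > 0")
  structure(list(base_params = base_params, n_points = n_points,
                 shear_range = as.numeric(shear_range),
                 noise_sd = noise_sd, bump_amplitude = bump_amplitude,
                 bump_center = bump_center, bump_width = bump_width,
                 seed = as.integer(seed),
                 mixed_tantalum = isTRUE(mixed_tantalum)),
            class = "synthetic_rheometry_config")
}

# run code under a local RNG state without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate one synthetic flow curve
#'
#' @param config A [synthetic_rheometry_config].
#' @return A [rheometry_curve]. With `noise_sd = 0` and `bump_amplitude = 0`
#'   the curve equals the base Sisko law pointwise; the same config (same
#'   seed) always yields the identical curve.
#' @export
generate_curve <- function(config) {
  stopifnot(inherits(config, "synthetic_rheometry_config"))
  U <- 10^seq(log10(config$shear_range[1]), log10(config$shear_range[2]),
              length.out = config$n_points)
  base <- eval_sisko(config$base_params, U)
  dip <- 1 - config$bump_amplitude *
    exp(-(log10(U) - log10(config$bump_center))^2 / (2 * config$bump_width^2))
  eps <- if (config$noise_sd > 0) {
    with_local_seed(config$seed,
                    exp(stats::rnorm(length(U), 0, config$noise_sd)))
  } else rep(1, length(U))
  rheometry_curve(U, base * dip * eps,
                  temperature = config$base_params$temperature,
                  polymer_label = config$base_params$polymer_label,
                  mixed_tantalum = config$mixed_tantalum)
}

#' Generate a collection of flow curves
#'
#' One curve per configuration; optionally written out in the flow-curve CSV
#' dialect (see [write_flow_curves()]). Duplicate
#' (polymer, temperature, tantalum) labels only raise a warning: replicate
#' measurements of one sample are legitimate.
#'
#' @param configs Non-empty list of [synthetic_rheometry_config] objects.
#' @param file Optional path of a CSV file to write.
#' @return List of [rheometry_curve] objects (invisibly if written).
#' @export
generate_dataset <- function(configs, file = NULL) {
  if (!is.list(configs) || length(configs) == 0 ||
      inherits(configs, "synthetic_rheometry_config"))
    stop("`configs` must be a non-empty list of configurations")
  ok <- vapply(configs, inherits, logical(1), "synthetic_rheometry_config")
  if (!all(ok)) stop("all elements must be synthetic_rheometry_config objects")
  curves <- lapply(configs, generate_curve)
  keys <- vapply(curves, function(cu)
    paste(cu$polymer_label, cu$temperature, cu$mixed_tantalum, sep = "|"),
    character(1))
  if (anyDuplicated(keys))
    warning("duplicate (polymer, temperature, tantalum) labels: ",
            paste(unique(keys[duplicated(keys)]), collapse = "; "))
  if (!is.null(file)) {
    write_flow_curves(curves, file)
    return(invisible(curves))
  }
  curves
}

#' Base parameters of the unmixed-tantalum sample variant
#'
#' When the tantalum powder is not agitated into suspension, the sheared
#' sample is essentially the clear copolymer/DMSO solution; measured curves
#' of the two variants agree near the high-shear plateau but diverge most
#' strongly below 1 1/s. The shipped variant keeps `mu0` and halves the
#' consistency coefficient `k`, so the viscosity ratio between variants
#' departs from 1 as shear rate decreases.
#'
#' @param params Mixed-sample [sisko_params].
#' @return [sisko_params] of the unmixed variant.
#' @export
unmixed_tantalum_params <- function(params) {
  stopifnot(inherits(params, "sisko_params"))
  sisko_params(params$mu0, params$k * 0.5, params$n,
               temperature = params$temperature,
               polymer_label = params$polymer_label)
}
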