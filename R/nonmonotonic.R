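#' Detect the nonmonotonic viscosity zone of a flow curve
#'
#' Measured flow curves of these agents show a zone of nonmonotonic
#' dependence of viscosity on shear rate near 1 1/s, most pronounced at
#' physiological temperature: as the polymer leaves the microcatheter into a
#' much wider vessel its shear rate traverses this zone and viscosity drops
#' by roughly 30 percent. This detector locates that zone on a (possibly
#' noisy) flow curve.
#'
#' The curve is first smoothed with a short moving median (robust to
#' single-point instrument spikes), then compared with its best
#' monotone-decreasing least-squares approximation (antitonic regression).
#' A dip is the point lying furthest below that monotone envelope; the
#' preceding shoulder -- the operational "local maximum" -- is the last point
#' before the dip still at the height of the post-dip recovery peak. On a
#' monotone curve the envelope residual vanishes and no zone is reported.
#'
#' @param curve A [rheometry_curve].
#' @param search_window Shear-rate interval (1/s) to search; default
#'   `c(0.1, 10)`.
#' @param smoothing_window Odd integer width of the moving median; default 3
#'   (one grid step each side at the usual ~10 points/decade sampling; wider
#'   windows erode the dip itself). Use 1 to disable smoothing.
#' @param min_drop Minimum relative dip depth (default 0.05) below which the
#'   curve is declared monotone; rejects ordinary multiplicative instrument
#'   noise.
#' @return A `nonmonotonic_zone` object (fields `shear_at_local_max`,
#'   `shear_at_local_min`, `relative_drop`), or `NULL` when the smoothed
#'   curve is monotone. Absence of a zone is a valid result, not an error.
#' @export
detect_nonmonotonic_zone <- function(curve, search_window = c(0.1, 10),
                                     smoothing_window = 3, min_drop = 0.05) {
  stopifnot(inherits(curve, "rheometry_curve"))
  if (length(search_window) != 2 || search_window[1] >= search_window[2])
    stop("`search_window` must be an increasing length-2 interval")
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 1 || smoothing_window %% 2 == 0)
    stop("`smoothing_window` must be a positive odd integer")
  if (min_drop <= 0 || min_drop >= 1)
    stop("`min_drop` must be in (0, 1)")

  m <- if (smoothing_window > 1) {
    as.numeric(stats::runmed(curve$viscosities, smoothing_window,
                             endrule = "median"))
  } else curve$viscosities
  keep <- curve$shear_rates >= search_window[1] &
    curve$shear_rates <= search_window[2]
  if (sum(keep) < 3) stop("`search_window` contains fewer than 3 points")
  U <- curve$shear_rates[keep]; m <- m[keep]
  nk <- length(m)

  # best monotone-decreasing approximation (antitonic regression)
  env <- -stats::isoreg(seq_len(nk), -m)$yf
  r <- m / env - 1
  j <- which.min(r)
  if (j <= 1 || j >= nk || r[j] > -min_drop) return(NULL)

  j2 <- j + which.max(m[(j + 1):nk])           # recovery peak after the dip
  before <- which(m[seq_len(j - 1)] >= m[j2])  # shoulder at recovery height
  i <- if (length(before)) max(before) else which.max(r[seq_len(j - 1)])
  drop <- (m[i] - m[j]) / m[i]
  if (drop < min_drop) return(NULL)

  structure(list(shear_at_local_max = U[i],
                 shear_at_local_min = U[j],
                 relative_drop = drop),
            class = "nonmonotonic_zone")
}

#' @export
print.nonmonotonic_zone <- function(x, ...) {
  cat(sprintf(
    "Nonmonotonic viscosity zone: shoulder at %.3g 1/s, dip at %.3g 1/s, relative drop %.1f%%\n",
    x$shear_at_local_max, x$shear_at_local_min, 100 * x$relative_drop))
  invisible(x)
}
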