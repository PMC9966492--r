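#' Read flow curves from CSV
#'
#' Reads the flow-curve dialect: a UTF-8 CSV with header
#' `shear_rate_per_s,viscosity_mPas,temperature_C,polymer,mixed_tantalum`,
#' one measurement point per row, dot decimal separator. Rows are grouped
#' into one curve per (polymer, temperature, tantalum) combination.
#' Malformed content is reported with the offending line number.
#'
#' @param file Path to the CSV file.
#' @return Named list of [rheometry_curve] objects.
#' @export
read_flow_curves <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file)
  df <- tryCatch(
    utils::read.csv(file, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("cannot parse '", file, "': ",
                             conditionMessage(e)))
  wanted <- c("shear_rate_per_s", "viscosity_mPas", "temperature_C",
              "polymer", "mixed_tantalum")
  if (!identical(sort(names(df)), sort(wanted)))
    stop("'", file, "' line 1: expected header ",
         paste(wanted, collapse = ","), " but found ",
         paste(names(df), collapse = ","))
  if (nrow(df) == 0) stop("'", file, "': no measurement rows")
  for (col in c("shear_rate_per_s", "viscosity_mPas", "temperature_C")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("'", file, "' line ", bad[1] + 1, ": non-numeric value '",
           df[[col]][bad[1]], "' in column ", col)
    df[[col]] <- v
  }
  mt <- toupper(trimws(df$mixed_tantalum)) %in% c("TRUE", "T", "1", "YES")
  df$mixed_tantalum <- mt

  key <- paste(df$polymer, df$temperature_C, df$mixed_tantalum, sep = "|")
  groups <- split(df, factor(key, levels = unique(key)))
  curves <- lapply(groups, function(g)
    rheometry_curve(g$shear_rate_per_s, g$viscosity_mPas,
                    temperature = g$temperature_C[1],
                    polymer_label = g$polymer[1],
                    mixed_tantalum = g$mixed_tantalum[1]))
  names(curves) <- names(groups)
  curves
}

#' Write flow curves to CSV
#'
#' Writes one or several curves in the flow-curve CSV dialect understood by
#' [read_flow_curves()].
#'
#' @param curves A [rheometry_curve] or a list of them.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_flow_curves <- function(curves, file) {
  if (inherits(curves, "rheometry_curve")) curves <- list(curves)
  stopifnot(all(vapply(curves, inherits, logical(1), "rheometry_curve")))
  df <- do.call(rbind, lapply(curves, as.data.frame))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Fit the Sisko model to every curve in a flow-curve file
#'
#' Driver for batch fitting: reads the file, fits each
#' (polymer, temperature) group with [fit_sisko()], and returns (optionally
#' writes) the fitted-parameter report with header
#' `polymer,temperature_C,mu0_mPas,k,n,residual,converged`.
#'
#' @param file Flow-curve CSV path.
#' @param shear_window Fitting window, as in [fit_sisko()].
#' @param out Optional path of the report CSV to write.
#' @return data.frame report, one row per curve. An attribute
#'   `all_converged` summarizes convergence across rows.
#' @export
fit_flow_curve_file <- function(file, shear_window = c(0.1, 10), out = NULL) {
  curves <- read_flow_curves(file)
  rows <- lapply(curves, function(cu) {
    fit <- fit_sisko(cu, shear_window)
    data.frame(polymer = cu$polymer_label, temperature_C = cu$temperature,
               mu0_mPas = fit$params$mu0, k = fit$params$k, n = fit$params$n,
               residual = fit$residual, converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "all_converged") <- all(report$converged)
  if (!is.null(out)) utils::write.csv(report, out, row.names = FALSE,
                                      quote = FALSE)
  report
}
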