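#' Quasi-static pressure-radius curve
#'
#' Container for a tabulated transmural pressure versus radius recording of
#' one airway (measured, e.g. by ultrasound during a slow pressure ramp, or
#' synthetic). Pressures must be strictly monotone within the curve; the
#' expiratory limb is conventionally stored from high to low pressure.
#'
#' @param p_tm Transmural pressures in kPa (strictly monotone).
#' @param r_in Deformed inner radii in mm.
#' @param r_out Deformed outer radii in mm, or `NULL` if not recorded.
#' @param lambda_z Axial stretch ratio held during acquisition.
#' @param label Identifier for the airway.
#' @return An object of class `"pressure_radius_curve"` (a data frame with
#'   columns `p_tm`, `r_in`, `r_out` and attributes `lambda_z`, `label`).
#' @export
pressure_radius_curve <- function(p_tm, r_in, r_out = NULL, lambda_z = 1,
                                  label = "airway") {
  stopifnot(is.numeric(p_tm), is.numeric(r_in),
            length(p_tm) == length(r_in), lambda_z > 0)
  d <- diff(p_tm)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("'p_tm' must be strictly monotone within a curve")
  if (is.null(r_out)) r_out <- rep(NA_real_, length(p_tm))
  if (length(r_out) != length(p_tm))
    stop("'r_out' must match the length of 'p_tm'")
  bad <- which(!is.na(r_out) & r_out <= r_in)
  if (length(bad))
    stop("r_out must exceed r_in (violated at record ",
         paste(bad, collapse = ", "), ")")
  structure(data.frame(p_tm = p_tm, r_in = r_in, r_out = r_out),
            lambda_z = lambda_z, label = as.character(label),
            class = c("pressure_radius_curve", "data.frame"))
}

#' @export
print.pressure_radius_curve <- function(x, ...) {
  cat(sprintf(
    "Pressure-radius curve '%s': %d records, p_tm %.3g to %.3g kPa, lambda_z = %.3g\n",
    attr(x, "label"), nrow(x), x$p_tm[1], x$p_tm[nrow(x)],
    attr(x, "lambda_z")))
  invisible(x)
}

#' @export
plot.pressure_radius_curve <- function(x, ...,
                                       xlab = "Transmural pressure (kPa)",
                                       ylab = "Inner radius (mm)") {
  graphics::plot(x$p_tm, x$r_in, xlab = xlab, ylab = ylab,
                 col = "red", ...)
  invisible(x)
}

#' Read a pressure-radius curve from CSV
#'
#' Expects a header with columns `p_tm_kpa`, `r_in_mm` and optionally
#' `r_out_mm` and a constant `lambda_z` column (a per-file sidecar field;
#' an explicit `lambda_z` argument overrides it).
#'
#' @param path CSV file path.
#' @param lambda_z Axial stretch during acquisition; if `NULL`, taken from
#'   a `lambda_z` column, defaulting to 1.
#' @param label Curve label; defaults to the file name.
#' @return A [pressure_radius_curve()].
#' @export
read_pressure_radius_csv <- function(path, lambda_z = NULL, label = NULL) {
  df <- .read_strict_csv(path, required = c("p_tm_kpa", "r_in_mm"))
  if (is.null(lambda_z)) {
    lambda_z <- if ("lambda_z" %in% names(df)) {
      lz <- unique(df$lambda_z)
      if (length(lz) != 1L)
        stop("column 'lambda_z' must be constant within ", path)
      lz
    } else 1
  }
  if (is.null(label))
    label <- sub("\\.csv$", "", basename(path))
  r_out <- if ("r_out_mm" %in% names(df)) df$r_out_mm else NULL
  pressure_radius_curve(df$p_tm_kpa, df$r_in_mm, r_out,
                        lambda_z = lambda_z, label = label)
}

#' Write a pressure-radius curve to CSV
#'
#' Writes columns `p_tm_kpa`, `r_in_mm`, `r_out_mm`, `lambda_z` with a
#' header, "." decimal separator, UTF-8.
#'
#' @param curve A [pressure_radius_curve()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pressure_radius_csv <- function(curve, path) {
  stopifnot(inherits(curve, "pressure_radius_curve"))
  df <- data.frame(p_tm_kpa = curve$p_tm, r_in_mm = curve$r_in,
                   r_out_mm = curve$r_out,
                   lambda_z = attr(curve, "lambda_z"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Stress-free reference geometry from a measured curve
#'
#' Takes the inner and outer radii of the record at (or within 0.05 kPa
#' of) zero transmural pressure and maps them back through the axial
#' pre-stretch to the unloaded, unstretched reference. The mapping
#' `r = R * sqrt(lambda_z)` is exact: uniaxial extension of an
#' incompressible isotropic tube is a traction-free universal solution, so
#' the zero-pressure record at stretch `lambda_z` corresponds exactly to a
#' stress-free cylinder with those scaled radii.
#'
#' @param curve A [pressure_radius_curve()] with recorded outer radii.
#' @param p_tol Maximum |p_tm| of the record accepted as "zero pressure".
#' @return An [airway_geometry()].
#' @export
extract_reference_geometry <- function(curve, p_tol = 0.05) {
  stopifnot(inherits(curve, "pressure_radius_curve"))
  i <- which.min(abs(curve$p_tm))
  if (abs(curve$p_tm[i]) > p_tol)
    stop(sprintf(
      "no record within %.3g kPa of zero transmural pressure (closest: %.3g kPa)",
      p_tol, curve$p_tm[i]))
  if (is.na(curve$r_out[i]))
    stop("the zero-pressure record has no outer radius; ",
         "r_out is required to infer the reference geometry")
  lz <- attr(curve, "lambda_z")
  airway_geometry(curve$r_in[i] * sqrt(lz), curve$r_out[i] * sqrt(lz))
}
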