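#' Undeformed (stress-free) airway geometry
#'
#' The reference configuration of a single airway modelled as a
#' thick-walled cylinder: inner radius, outer radius and length in the
#' unloaded, axially unstretched state.
#'
#' @param r_in Undeformed inner radius in mm; `0 < r_in < r_out`.
#' @param r_out Undeformed outer radius in mm.
#' @param length Undeformed length in mm (defaults to 1; the plane-strain
#'   analysis is per unit length).
#' @return An object of class `"airway_geometry"`.
#' @export
airway_geometry <- function(r_in, r_out, length = 1) {
  stopifnot(is.numeric(r_in), is.numeric(r_out), is.numeric(length))
  if (!(r_in > 0 && r_out > r_in)) stop("need 0 < r_in < r_out (mm)")
  if (length <= 0) stop("'length' must be > 0 (mm)")
  structure(list(r_in = r_in, r_out = r_out, length = length),
            class = "airway_geometry")
}

#' @export
print.airway_geometry <- function(x, ...) {
  cat(sprintf(
    "Airway reference geometry: r_in = %.4g mm, r_out = %.4g mm (wall/lumen = %.3g)\n",
    x$r_in, x$r_out, (x$r_out - x$r_in) / x$r_in))
  invisible(x)
}

# undeformed wall cross-section area, mm^2
.wall_area_ref <- function(ref) pi * (ref$r_out^2 - ref$r_in^2)

#' Deformed radius of a material point
#'
#' Maps an undeformed radial position `r` to its deformed position `R`
#' under the incompressible, axisymmetric, plane-strain deformation with
#' deformed inner radius `R_in` and axial stretch `lambda_z`:
#' \eqn{R = \sqrt{R_{in}^2 + (r^2 - r_{in}^2)/\lambda_z}}.
#'
#' @param r Undeformed radial position(s) in mm, within `[r_in, r_out]`.
#' @param ref An [airway_geometry()] object.
#' @param R_in Deformed inner radius in mm.
#' @param lambda_z Axial stretch ratio.
#' @return Deformed radius R in mm, monotone increasing in `r`.
#' @export
deformed_radius_at <- function(r, ref, R_in, lambda_z) {
  stopifnot(inherits(ref, "airway_geometry"), R_in > 0, lambda_z > 0)
  if (any(r < ref$r_in - 1e-12) || any(r > ref$r_out + 1e-12))
    stop("'r' must lie within [r_in, r_out]")
  arg <- R_in^2 + (r^2 - ref$r_in^2) / lambda_z
  if (any(arg < 0)) stop("invalid geometry: negative argument under the root")
  sqrt(arg)
}

#' Stretch ratios and first invariant at a wall point
#'
#' Computes the circumferential, radial and axial stretch ratios and the
#' first strain invariant at a material point with deformed radius `R` and
#' undeformed radius `r`. Incompressibility fixes
#' `lambda_r = 1/(lambda_theta * lambda_z)` so the product of the three
#' stretches is exactly 1, and `I1 = lambda_theta^2 + lambda_r^2 +
#' lambda_z^2`.
#'
#' @param R Deformed radius in mm.
#' @param r Undeformed radius in mm.
#' @param lambda_z Axial stretch ratio.
#' @return An object of class `"kinematic_point"`: list with
#'   `lambda_theta`, `lambda_r`, `lambda_z`, `I1`.
#' @export
kinematics_at <- function(R, r, lambda_z) {
  stopifnot(all(R > 0), all(r > 0), lambda_z > 0)
  lt <- R / r
  lr <- 1 / (lt * lambda_z)
  structure(list(lambda_theta = lt, lambda_r = lr, lambda_z = lambda_z,
                 I1 = lt^2 + lr^2 + lambda_z^2),
            class = "kinematic_point")
}
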