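#' Constitutive parameters of the airway wall
#'
#' Bundles the three material constants of the strain-energy density
#' function used throughout the package: `k1` (kPa) sets the ground-state
#' stiffness governing distensibility at low transmural pressure, while
#' `k2` (dimensionless) and `k3` (kPa) control the exponential
#' strain-stiffening that produces the noncompliant plateau of the
#' pressure-radius curve at high pressure.
#'
#' @param k1 Stress-like stiffness in kPa; must be > 0.
#' @param k2 Dimensionless stiffening exponent; must be > 0.
#' @param k3 Stress-like stiffening amplitude in kPa; must be >= 0.
#'
#' @return An object of class `"airway_material"`: a named list with
#'   elements `k1`, `k2`, `k3`.
#' @examples
#' m <- airway_material(k1 = 4, k2 = 0.6, k3 = 24)
#' sedf(3.2, m)
#' @export
airway_material <- function(k1, k2, k3) {
  stopifnot(is.numeric(k1), length(k1) == 1L, is.finite(k1),
            is.numeric(k2), length(k2) == 1L, is.finite(k2),
            is.numeric(k3), length(k3) == 1L, is.finite(k3))
  if (k1 <= 0) stop("'k1' must be > 0 (kPa)")
  if (k2 <= 0) stop("'k2' must be > 0")
  if (k3 < 0) stop("'k3' must be >= 0 (kPa)")
  structure(list(k1 = k1, k2 = k2, k3 = k3), class = "airway_material")
}

#' @export
print.airway_material <- function(x, ...) {
  cat(sprintf("Airway wall material: k1 = %.4g kPa, k2 = %.4g, k3 = %.4g kPa\n",
              x$k1, x$k2, x$k3))
  invisible(x)
}

#' Strain-energy density of the airway wall
#'
#' Isotropic, incompressible strain-energy density expressed in the first
#' strain invariant `I1` only:
#' \deqn{W(I_1) = \tfrac{k_1}{2}(I_1 - 3) +
#'   \tfrac{k_3}{4 k_2}\left[e^{k_2 (I_1-3)^2} - 1\right].}
#' The linear term gives a nonzero ground-state stiffness (slope `k1/2`
#' at `I1 = 3`); the exponential term produces the highly nonlinear
#' stiffening regime. `W(3) = 0` and `W` is strictly increasing for
#' `I1 > 3`.
#'
#' @param I1 First strain invariant, `I1 >= 3`. Vectorized.
#' @param material An [airway_material()] object.
#' @return Strain energy density in kPa (energy per unit volume).
#' @seealso [sedf_prime()] for the analytic derivative dW/dI1.
#' @export
sedf <- function(I1, material) {
  stopifnot(inherits(material, "airway_material"))
  if (any(I1 < 3 - 1e-12)) stop("'I1' must be >= 3")
  x <- pmax(I1 - 3, 0)
  material$k1 / 2 * x +
    material$k3 / (4 * material$k2) * expm1(material$k2 * x^2)
}

#' Analytic derivative of the strain-energy density
#'
#' \eqn{dW/dI_1 = k_1/2 + (k_3/2)(I_1-3)\, e^{k_2 (I_1-3)^2}}. Strictly
#' positive for all admissible `I1`, equal to `k1/2` at the stress-free
#' reference.
#'
#' @inheritParams sedf
#' @return dW/dI1 in kPa. Vectorized.
#' @export
sedf_prime <- function(I1, material) {
  stopifnot(inherits(material, "airway_material"))
  if (any(I1 < 3 - 1e-12)) stop("'I1' must be >= 3")
  x <- pmax(I1 - 3, 0)
  material$k1 / 2 + material$k3 / 2 * x * exp(material$k2 * x^2)
}

# second derivative d2W/dI1^2, used by the Newton pressure solver and the
# analytic pieces of the incremental modulus
.sedf_second <- function(I1, material) {
  x <- pmax(I1 - 3, 0)
  material$k3 / 2 * exp(material$k2 * x^2) * (1 + 2 * material$k2 * x^2)
}
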