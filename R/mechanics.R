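# Core thick-walled-cylinder mechanics: pressure integral, inverse solver,
# transmural stress profile, incremental modulus, compliance and strain.
#
# Sign convention: P_TM = P_in - P_out with P_out = 0 kPa throughout, so
# sigma_r(R_in) = -P_TM (compression negative) and sigma_r(R_out) = 0.
# Units: kPa for pressures/stresses, mm for lengths.

.airwaymech_env <- new.env(parent = emptyenv())

# cached Gauss-Legendre nodes/weights on [-1, 1]
.gl_rule <- function(n = 64L) {
  key <- paste0("gl", n)
  rule <- .airwaymech_env[[key]]
  if (is.null(rule)) {
    rule <- pracma::gaussLegendre(n, -1, 1)
    .airwaymech_env[[key]] <- rule
  }
  rule
}

# Pressure integral pulled back to the undeformed radius, where the limits
# do not depend on R_in:
#   P_in(R_in) = int_{r_in}^{r_out} dsigma(r) * r / (lambda_z * R(r)^2) dr
# with R(r)^2 = R_in^2 + (r^2 - r_in^2)/lambda_z and
# dsigma = sigma_theta - sigma_r = 2 (lambda_theta^2 - lambda_r^2) W'(I1).
# Fixed 64-node Gauss-Legendre; optionally returns the analytic dP/dR_in
# for the safeguarded Newton solver.
.pressure_gauss <- function(R_in, ref, lambda_z, material, deriv = FALSE,
                            n_nodes = 64L) {
  rule <- .gl_rule(n_nodes)
  half <- (ref$r_out - ref$r_in) / 2
  r <- (ref$r_out + ref$r_in) / 2 + half * rule$x
  w <- half * rule$w
  lz2 <- lambda_z^2

  R2 <- R_in^2 + (r^2 - ref$r_in^2) / lambda_z
  lt2 <- R2 / r^2
  lr2 <- 1 / (lt2 * lz2)
  I1 <- lt2 + lr2 + lz2
  Wp <- sedf_prime(I1, material)
  dsig <- 2 * (lt2 - lr2) * Wp
  g <- dsig * r / (lambda_z * R2)
  P <- sum(w * g)
  if (!deriv) return(P)

  dR2 <- 2 * R_in                       # d(R^2)/dR_in
  dlt2 <- dR2 / r^2
  dlr2 <- -lr2 / lt2 * dlt2
  dI1 <- dlt2 + dlr2
  Wpp <- .sedf_second(I1, material)
  ddsig <- 2 * (dlt2 - dlr2) * Wp + 2 * (lt2 - lr2) * Wpp * dI1
  dg <- ddsig * r / (lambda_z * R2) - dsig * r * dR2 / (lambda_z * R2^2)
  list(P = P, dP = sum(w * dg))
}

# stress difference sigma_theta - sigma_r at deformed radius R (vectorized),
# given the reference geometry and inner deformed radius implied by R itself
# through the closed-form inverse map r(R).
.stress_diff_at_R <- function(R, R_in, ref, lambda_z, material) {
  r2 <- ref$r_in^2 + lambda_z * (R^2 - R_in^2)
  lt2 <- R^2 / r2
  lr2 <- 1 / (lt2 * lambda_z^2)
  I1 <- lt2 + lr2 + lambda_z^2
  2 * (lt2 - lr2) * sedf_prime(I1, material)
}

#' Stress difference at a wall point
#'
#' Circumferential minus radial Cauchy stress at a material point. The
#' incompressibility multiplier cancels in the difference, leaving
#' \eqn{\sigma_\theta - \sigma_r = 2(\lambda_\theta^2 - \lambda_r^2)\,
#' dW/dI_1} for an I1-only strain-energy function. Zero at the undeformed
#' state and positive whenever `lambda_theta > lambda_r`.
#'
#' @param kin A [kinematics_at()] object.
#' @param material An [airway_material()] object.
#' @return `sigma_theta - sigma_r` in kPa.
#' @export
stress_difference <- function(kin, material) {
  stopifnot(inherits(kin, "kinematic_point"))
  2 * (kin$lambda_theta^2 - kin$lambda_r^2) * sedf_prime(kin$I1, material)
}

#' Luminal pressure sustained by a deformed airway
#'
#' The transmural (luminal, with outer pressure 0) pressure in equilibrium
#' with a given deformed inner radius, obtained by integrating radial
#' equilibrium across the wall:
#' \deqn{P_{in} = \int_{R_{in}}^{R_{out}}
#'   \frac{\sigma_\theta - \sigma_r}{R}\, dR.}
#' The integral is evaluated on the undeformed radial coordinate (fixed
#' limits) with adaptive Gauss-Kronrod quadrature by default; a fixed
#' 64-node Gauss-Legendre rule is used as fallback and by the internal
#' solvers.
#'
#' @param R_in Deformed inner radius in mm.
#' @param ref An [airway_geometry()] object.
#' @param lambda_z Axial stretch ratio.
#' @param material An [airway_material()] object.
#' @param abs_tol Absolute quadrature tolerance in kPa.
#' @param method `"adaptive"` (default) or `"gauss"`.
#' @return Luminal pressure P_in in kPa. Negative values indicate a
#'   configuration compressed below its zero-pressure radius.
#' @export
luminal_pressure <- function(R_in, ref, lambda_z, material,
                             abs_tol = 1e-8, method = c("adaptive", "gauss")) {
  stopifnot(inherits(ref, "airway_geometry"), R_in > 0, lambda_z > 0)
  method <- match.arg(method)
  if (method == "gauss")
    return(.pressure_gauss(R_in, ref, lambda_z, material))
  integrand <- function(r) {
    R2 <- R_in^2 + (r^2 - ref$r_in^2) / lambda_z
    lt2 <- R2 / r^2
    lr2 <- 1 / (lt2 * lambda_z^2)
    I1 <- lt2 + lr2 + lambda_z^2
    2 * (lt2 - lr2) * sedf_prime(I1, material) * r / (lambda_z * R2)
  }
  res <- tryCatch(
    stats::integrate(integrand, ref$r_in, ref$r_out, abs.tol = abs_tol,
                     rel.tol = .Machine$double.eps^0.5),
    error = function(e) NULL)
  if (is.null(res) || res$message != "OK")
    return(.pressure_gauss(R_in, ref, lambda_z, material))
  res$value
}

# zero-pressure deformed inner radius under pure axial stretch: uniaxial
# extension of an incompressible isotropic tube is an exact traction-free
# solution, R = r / sqrt(lambda_z)
.zero_pressure_radius <- function(ref, lambda_z) ref$r_in / sqrt(lambda_z)

#' Solve the deformed state at a prescribed transmural pressure
#'
#' Inverts the pressure-radius relation: finds the deformed inner radius at
#' which [luminal_pressure()] equals `p_tm`, then completes the state via
#' incompressibility. Root-finding is safeguarded Newton within a bracket
#' grown geometrically from the exact zero-pressure radius
#' `r_in/sqrt(lambda_z)`; the strain-stiffening material makes the
#' pressure-radius map strictly monotone so the root is unique.
#'
#' @param p_tm Transmural pressure in kPa; must be >= 0 (the
#'   negative-pressure branch requires a different material description and
#'   is rejected).
#' @param ref An [airway_geometry()] object.
#' @param lambda_z Axial stretch ratio.
#' @param material An [airway_material()] object.
#' @param tol Convergence tolerance on the pressure residual in kPa.
#' @return An object of class `"deformation_state"`: list with `p_tm`,
#'   `R_in`, `R_out`, `lambda_z`.
#' @export
solve_deformed_state <- function(p_tm, ref, lambda_z, material, tol = 1e-9) {
  stopifnot(inherits(ref, "airway_geometry"), lambda_z > 0)
  if (p_tm < 0)
    stop("negative transmural pressure is outside the model's validity; ",
         "only p_tm >= 0 is supported")
  R0 <- .zero_pressure_radius(ref, lambda_z)
  if (p_tm == 0) return(.deformation_state(0, R0, ref, lambda_z))

  lo <- R0; p_lo <- 0
  hi <- R0 * 1.05
  p_hi <- .pressure_gauss(hi, ref, lambda_z, material)
  n_exp <- 0L
  while (p_hi < p_tm) {
    lo <- hi; p_lo <- p_hi
    hi <- hi * 1.3
    p_hi <- .pressure_gauss(hi, ref, lambda_z, material)
    n_exp <- n_exp + 1L
    if (n_exp > 80L)
      stop(sprintf(
        "bracket expansion failed at p_tm = %.4g kPa (r_in = %.4g mm, r_out = %.4g mm): max pressure reached %.4g kPa",
        p_tm, ref$r_in, ref$r_out, p_hi))
  }

  R <- lo + (hi - lo) * (p_tm - p_lo) / max(p_hi - p_lo, .Machine$double.xmin)
  for (iter in 1:100) {
    pd <- .pressure_gauss(R, ref, lambda_z, material, deriv = TRUE)
    f <- pd$P - p_tm
    if (abs(f) < tol) return(.deformation_state(p_tm, R, ref, lambda_z))
    if (f > 0) hi <- R else lo <- R
    step <- f / pd$dP
    R_new <- R - step
    if (!is.finite(R_new) || R_new <= lo || R_new >= hi)
      R_new <- (lo + hi) / 2
    R <- R_new
  }
  stop(sprintf(
    "pressure-radius solver did not converge at p_tm = %.4g kPa (r_in = %.4g mm, r_out = %.4g mm)",
    p_tm, ref$r_in, ref$r_out))
}

.deformation_state <- function(p_tm, R_in, ref, lambda_z) {
  R_out <- sqrt(R_in^2 + (ref$r_out^2 - ref$r_in^2) / lambda_z)
  structure(list(p_tm = p_tm, R_in = R_in, R_out = R_out,
                 lambda_z = lambda_z),
            class = "deformation_state")
}

#' @export
print.deformation_state <- function(x, ...) {
  cat(sprintf(
    "Deformed airway state: p_tm = %.4g kPa, R_in = %.5g mm, R_out = %.5g mm, lambda_z = %.3g\n",
    x$p_tm, x$R_in, x$R_out, x$lambda_z))
  invisible(x)
}

#' Transmural Cauchy stress profile
#'
#' Radial, circumferential and axial Cauchy stresses across the deformed
#' wall of an equilibrated state. The incompressibility multiplier is
#' eliminated by integrating radial equilibrium inward from the luminal
#' boundary condition:
#' \deqn{\sigma_r(R) = -P_{TM} + \int_{R_{in}}^{R}
#'   \frac{\sigma_\theta - \sigma_r}{R'}\, dR',}
#' then \eqn{\sigma_\theta = \sigma_r + 2(\lambda_\theta^2 -
#' \lambda_r^2) W'} and \eqn{\sigma_z = \sigma_r + 2(\lambda_z^2 -
#' \lambda_r^2) W'}. At the outer surface `sigma_r` vanishes to quadrature
#' tolerance.
#'
#' @param state A [solve_deformed_state()] result (or any equilibrated
#'   `"deformation_state"`).
#' @param ref An [airway_geometry()] object.
#' @param material An [airway_material()] object.
#' @param n_points Number of radial sample points (>= 2).
#' @return An object of class `"wall_stress_profile"`: list with `radii`,
#'   `sigma_r`, `sigma_theta`, `sigma_z` (kPa).
#' @export
radial_stress_profile <- function(state, ref, material, n_points = 101L) {
  stopifnot(inherits(state, "deformation_state"),
            inherits(ref, "airway_geometry"))
  if (n_points < 2L) stop("'n_points' must be >= 2")
  lambda_z <- state$lambda_z
  radii <- seq(state$R_in, state$R_out, length.out = n_points)

  rule <- .gl_rule(32L)
  sig_r <- numeric(n_points)
  sig_r[1] <- -state$p_tm
  for (k in 2:n_points) {
    a <- state$R_in; b <- radii[k]
    half <- (b - a) / 2
    Rq <- (a + b) / 2 + half * rule$x
    f <- .stress_diff_at_R(Rq, state$R_in, ref, lambda_z, material) / Rq
    sig_r[k] <- -state$p_tm + sum(half * rule$w * f)
  }

  r2 <- ref$r_in^2 + lambda_z * (radii^2 - state$R_in^2)
  lt2 <- radii^2 / r2
  lr2 <- 1 / (lt2 * lambda_z^2)
  I1 <- lt2 + lr2 + lambda_z^2
  Wp <- sedf_prime(I1, material)
  sig_t <- sig_r + 2 * (lt2 - lr2) * Wp
  sig_z <- sig_r + 2 * (lambda_z^2 - lr2) * Wp

  structure(list(radii = radii, sigma_r = sig_r, sigma_theta = sig_t,
                 sigma_z = sig_z),
            class = "wall_stress_profile")
}

#' Circumferential stress at the inner wall
#'
#' \eqn{\sigma_\theta(R_{in}) = -P_{TM} + (\sigma_\theta -
#' \sigma_r)|_{R_{in}}}; the stress the luminal cell layer experiences, and
#' the quantity held fixed by the mechanical-homeostasis calibration.
#'
#' @inheritParams radial_stress_profile
#' @return Inner-wall circumferential Cauchy stress in kPa.
#' @export
circumferential_stress_inner <- function(state, ref, material) {
  stopifnot(inherits(state, "deformation_state"))
  -state$p_tm +
    .stress_diff_at_R(state$R_in, state$R_in, ref, state$lambda_z, material)
}

# sigma_theta at the inner wall as a function of the inner radius along the
# inflation path: sigma_theta(R) = dsigma(R) - P(R)
.sigma_inner_at_radius <- function(R_in, ref, lambda_z, material) {
  .stress_diff_at_R(R_in, R_in, ref, lambda_z, material) -
    .pressure_gauss(R_in, ref, lambda_z, material)
}

#' Incremental circumferential elastic modulus
#'
#' The operating-point stiffness of the airway wall: the slope of the
#' inner-wall circumferential stress versus circumferential stretch curve
#' along the quasi-static inflation path,
#' \eqn{Y_{inc} = d\sigma_\theta(R_{in}) / d\lambda_\theta(R_{in})},
#' evaluated by central finite difference on `lambda_theta` (one-sided near
#' the zero-pressure limit, where the lower perturbation would cross into
#' the negative-pressure branch).
#'
#' @param p_tm Transmural pressure in kPa, in `[0, 3]`.
#' @param ref An [airway_geometry()] object.
#' @param lambda_z Axial stretch ratio.
#' @param material An [airway_material()] object.
#' @param rel_step Relative finite-difference step on `lambda_theta`.
#' @return Incremental modulus Y_inc in kPa (positive).
#' @export
incremental_modulus <- function(p_tm, ref, lambda_z, material,
                                rel_step = 1e-4) {
  stopifnot(p_tm >= 0)
  st <- solve_deformed_state(p_tm, ref, lambda_z, material)
  lt <- st$R_in / ref$r_in
  h <- rel_step * lt
  R_plus <- ref$r_in * (lt + h)
  R_minus <- ref$r_in * (lt - h)
  s_plus <- .sigma_inner_at_radius(R_plus, ref, lambda_z, material)
  if (.pressure_gauss(R_minus, ref, lambda_z, material) < 0) {
    # one-sided fallback: the lower point would be at negative pressure
    s0 <- .sigma_inner_at_radius(st$R_in, ref, lambda_z, material)
    return((s_plus - s0) / h)
  }
  s_minus <- .sigma_inner_at_radius(R_minus, ref, lambda_z, material)
  (s_plus - s_minus) / (2 * h)
}

#' Specific airway compliance
#'
#' Change in inner-wall circumferential stretch per unit transmural
#' pressure, \eqn{\Delta\lambda_\theta / \Delta P_{TM}}, over a pressure
#' window (default 0 to 3 kPa, the full breathing range). The stretch is
#' referenced to the undeformed inner radius.
#'
#' @param ref An [airway_geometry()] object.
#' @param lambda_z Axial stretch ratio.
#' @param material An [airway_material()] object.
#' @param p_lo,p_hi Pressure window bounds in kPa, `p_lo < p_hi`.
#' @return Specific compliance in 1/kPa.
#' @export
specific_compliance <- function(ref, lambda_z, material, p_lo = 0, p_hi = 3) {
  if (!(p_lo < p_hi)) stop("'p_lo' must be < 'p_hi'")
  R_lo <- solve_deformed_state(p_lo, ref, lambda_z, material)$R_in
  R_hi <- solve_deformed_state(p_hi, ref, lambda_z, material)$R_in
  ((R_hi - R_lo) / ref$r_in) / (p_hi - p_lo)
}

#' Parenchymal hole expansion benchmark
#'
#' The generally accepted upper limit of airway expansion: if the
#' parenchymal hole around an airway expands isotropically with the lung,
#' and lung volume at 0 kPa transmural pressure is a fraction
#' `volume_fraction` (default 15%) of its volume at 3 kPa, the linear
#' expansion between the two pressures is `(1/volume_fraction)^(1/3)`.
#' Expressed as a specific compliance over the same window for direct
#' comparison with [specific_compliance()].
#'
#' @param p_lo,p_hi Pressure window in kPa.
#' @param volume_fraction Lung volume at `p_lo` as a fraction of volume at
#'   `p_hi`.
#' @return Benchmark compliance in 1/kPa.
#' @export
parenchymal_hole_compliance <- function(p_lo = 0, p_hi = 3,
                                        volume_fraction = 0.15) {
  stopifnot(p_lo < p_hi, volume_fraction > 0, volume_fraction < 1)
  ((1 / volume_fraction)^(1 / 3) - 1) / (p_hi - p_lo)
}

#' Circumferential strain between two pressures
#'
#' Percent change in luminal radius between two transmural pressures,
#' `100 * (R_in(p2) - R_in(p1)) / R_in(p1)` — the strain airway wall cells
#' experience over a breathing manoeuvre (e.g. tidal breathing 0.5 to
#' 1 kPa; deep inspiration 0.5 to 3 kPa).
#'
#' @param p1,p2 Transmural pressures in kPa (>= 0).
#' @param ref An [airway_geometry()] object.
#' @param lambda_z Axial stretch ratio.
#' @param material An [airway_material()] object.
#' @return Strain in percent.
#' @export
strain_percent <- function(p1, p2, ref, lambda_z, material) {
  R1 <- solve_deformed_state(p1, ref, lambda_z, material)$R_in
  R2 <- solve_deformed_state(p2, ref, lambda_z, material)$R_in
  100 * (R2 - R1) / R1
}
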