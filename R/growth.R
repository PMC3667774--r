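# Growth from newborn to adult, and remodeling under chronic constriction:
# both move along the wall-area-to-material-parameter relationship fitted
# to the calibrated adult tree.

#' Fit the growth law linking wall area to material parameters
#'
#' Least-squares log-log fit of the calibrated ground-state stiffness `k1`
#' (and, unless frozen, the stiffening exponent `k2`) against TLC wall
#' area across the generations of a calibrated adult tree. The same
#' fitted relationship is assumed to govern airway growth and
#' constriction-driven remodeling. Queries inside the fitted wall-area
#' range interpolate the law; queries outside extrapolate the log-linear
#' trend (or clamp, see [predict.growth_law()]), with a warning either
#' way.
#'
#' @param tree An `"airway_tree"` from [calibrate_tree()] with at least 5
#'   converged generations.
#' @param freeze_k2 If `TRUE`, `k2` is held at the tree's median value
#'   instead of varying along the law.
#' @return An object of class `"growth_law"`.
#' @export
fit_growth_law <- function(tree, freeze_k2 = FALSE) {
  stopifnot(inherits(tree, "airway_tree"))
  conv <- Filter(function(a) isTRUE(a$converged), tree$airways)
  if (length(conv) < 5L)
    stop("need at least 5 converged generations to fit the growth law")
  aw <- vapply(conv, function(a) a$record$wall_area_tlc, numeric(1))
  k1 <- vapply(conv, function(a) a$params$k1, numeric(1))
  k2 <- vapply(conv, function(a) a$params$k2, numeric(1))
  o <- order(aw)
  if (any(diff(k1[o]) <= 0))
    warning("calibrated k1 is not strictly increasing with wall area; ",
            "the fitted growth law enforces a monotone log-linear trend ",
            "through non-monotone points")
  fit1 <- stats::lm(log(k1) ~ log(aw))
  fit2 <- stats::lm(log(k2) ~ log(aw))
  # summary() warns on an exactly collinear (planted) relation; the zero
  # residual sd is then correct
  structure(list(
    coef_k1 = stats::coef(fit1),
    coef_k2 = stats::coef(fit2),
    sigma_k1 = suppressWarnings(summary(fit1)$sigma),
    sigma_k2 = suppressWarnings(summary(fit2)$sigma),
    k2_fixed = stats::median(k2),
    freeze_k2 = freeze_k2,
    k3_over_k1 = tree$spec$k3_over_k1,
    range_aw = range(aw),
    data = data.frame(wall_area = aw, k1 = k1, k2 = k2)),
    class = "growth_law")
}

#' @export
print.growth_law <- function(x, ...) {
  cat(sprintf(
    "Growth law over wall area %.3g-%.3g mm^2: log k1 = %.3g + %.3g log A_w (resid sd %.3g); k2 %s; k3 = %.3g k1\n",
    x$range_aw[1], x$range_aw[2], x$coef_k1[1], x$coef_k1[2], x$sigma_k1,
    if (x$freeze_k2) sprintf("frozen at %.3g", x$k2_fixed)
    else sprintf("log-linear (slope %.3g)", x$coef_k2[2]),
    x$k3_over_k1))
  invisible(x)
}

#' Material parameters implied by a wall area under the growth law
#'
#' @param object A [fit_growth_law()] result.
#' @param wall_area Wall area(s) at TLC in mm^2.
#' @param rule How to handle wall areas outside the fitted range:
#'   `"extrapolate"` (default) extends the log-linear trend with a
#'   warning; `"clamp"` holds the range-end values, also with a warning.
#' @param ... Unused.
#' @return A single [airway_material()] (or a list of them for vector
#'   input).
#' @export
predict.growth_law <- function(object, wall_area,
                               rule = c("extrapolate", "clamp"), ...) {
  rule <- match.arg(rule)
  outside <- wall_area < object$range_aw[1] | wall_area > object$range_aw[2]
  if (any(outside))
    warning(sprintf(
      "%d wall area(s) outside the fitted growth-law range [%.4g, %.4g] mm^2; %s",
      sum(outside), object$range_aw[1], object$range_aw[2],
      if (rule == "clamp") "clamped to the range ends"
      else "extrapolating the log-linear trend"))
  la <- if (rule == "clamp")
    log(pmin(pmax(wall_area, object$range_aw[1]), object$range_aw[2]))
  else log(wall_area)
  k1 <- exp(object$coef_k1[[1]] + object$coef_k1[[2]] * la)
  k2 <- if (object$freeze_k2) rep(object$k2_fixed, length(la))
        else exp(object$coef_k2[[1]] + object$coef_k2[[2]] * la)
  out <- lapply(seq_along(k1), function(i)
    airway_material(k1[i], k2[i], object$k3_over_k1 * k1[i]))
  if (length(out) == 1L) out[[1]] else out
}

#' Specific-compliance trajectory of one generation across growth
#'
#' For a given generation, takes its dimensions at each age stage
#' (newborn, child, adult), assigns material parameters from the growth
#' law, rebuilds the reference geometry from the TLC dimensions, and
#' computes the passive specific compliance over 0-3 kPa, normalised to
#' the newborn value (newborn = 1 exactly).
#'
#' @param generation Generation index present in all three tables.
#' @param age_tables Named list of [airway_dimension_table()] objects with
#'   elements `newborn`, `child`, `adult`.
#' @param law A [fit_growth_law()] result.
#' @param spec A [homeostasis_spec()].
#' @return Data frame with one row per stage: `stage`, `generation`,
#'   `wall_area`, `k1`, `compliance` (1/kPa), `normalized`.
#' @export
growth_trajectory <- function(generation, age_tables, law,
                              spec = homeostasis_spec()) {
  stages <- c("newborn", "child", "adult")
  if (!all(stages %in% names(age_tables)))
    stop("'age_tables' must contain newborn, child and adult tables")
  rows <- lapply(stages, function(st) {
    tbl <- age_tables[[st]]
    i <- which(tbl$generation == generation)
    if (!length(i))
      stop("generation ", generation, " missing from the ", st, " table")
    rec <- tbl[i, ]
    params <- suppressWarnings(predict(law, rec$wall_area_tlc))
    ref <- reference_from_tlc(rec, params, spec)
    data.frame(stage = st, generation = generation,
               wall_area = rec$wall_area_tlc, k1 = params$k1,
               compliance = specific_compliance(ref, spec$lambda_z,
                                                params, 0, spec$p_tlc))
  })
  out <- do.call(rbind, rows)
  out$normalized <- out$compliance / out$compliance[out$stage == "newborn"]
  out
}

#' Remodeling of an airway held at a chronically constricted radius
#'
#' Simulates structural remodeling under sustained smooth-muscle
#' constriction. The airway is held at a luminal radius reduced by
#' `constriction` (fraction of its baseline radius at the operating
#' pressure), so its inner wall sits at a reduced circumferential stretch
#' and its inner-wall stress falls below the homeostatic set-point.
#' Walking along the growth law parameterised by wall area — anchored at
#' the airway's own baseline `(A_w, k1, k2)` point so that zero
#' constriction maps to zero change — the function finds the wall area
#' whose implied (stiffer) material restores the set-point stress at the
#' constricted radius under the operating pressure. The constriction is
#' then removed (simulated bronchodilator) and the passive 0-3 kPa
#' specific compliance of the thicker, stiffer remodeled wall is compared
#' with baseline.
#'
#' Restoration is only possible while the held inner wall remains in
#' circumferential tension, i.e. while the held stretch exceeds
#' `1/sqrt(lambda_z)`; beyond that constriction level no stiffness can
#' restore a tensile set-point and the function raises an error reporting
#' the achievable stress range.
#'
#' @param airway A `"calibrated_airway"` (baseline adult generation).
#' @param constriction Fractional radius decrease, in (0, 0.6].
#' @param law A [fit_growth_law()] result.
#' @param spec A [homeostasis_spec()].
#' @param max_growth Bracket cap for the wall-area search, as a multiple
#'   of the baseline wall area.
#' @return An object of class `"remodeling_result"`: list with
#'   `constriction`, `wall_area` (mm^2), `params`, `d_compliance` and
#'   `d_wall_area` (fractional changes vs baseline), plus `baseline`
#'   values.
#' @export
chronic_constriction_remodel <- function(airway, constriction, law,
                                         spec = homeostasis_spec(),
                                         max_growth = 100) {
  stopifnot(inherits(airway, "calibrated_airway"),
            inherits(law, "growth_law"))
  if (!(constriction > 0 && constriction <= 0.6))
    stop("'constriction' must be in (0, 0.6]")
  lz <- spec$lambda_z
  r_in0 <- airway$ref$r_in
  R_op <- solve_deformed_state(spec$p_operating, airway$ref, lz,
                               airway$params)$R_in
  R_c <- (1 - constriction) * R_op
  A0 <- airway$record$wall_area_tlc
  c0 <- specific_compliance(airway$ref, lz, airway$params, 0, spec$p_tlc)

  # growth-law slopes anchored through the airway's own calibrated point
  material_at <- function(A) {
    k1 <- airway$params$k1 * (A / A0)^law$coef_k1[[2]]
    k2 <- if (law$freeze_k2) airway$params$k2
          else airway$params$k2 * (A / A0)^law$coef_k2[[2]]
    airway_material(k1, k2, law$k3_over_k1 * k1)
  }
  # inner-wall stress of the held state: radial boundary condition
  # -p_operating plus the constitutive stress difference at the held
  # circumferential stretch R_c/r_in0
  kin_c <- kinematics_at(R_c, r_in0, lz)
  sigma_held <- function(A) {
    -spec$p_operating + stress_difference(kin_c, material_at(A))
  }
  f <- function(A) sigma_held(A) - spec$sigma_setpoint
  f0 <- f(A0)
  hi <- A0
  f_hi <- f0
  while (f_hi < 0) {
    hi <- hi * 1.3
    if (hi > max_growth * A0) {
      # achievable ceiling: held stretch is at or below the tension
      # threshold, so stress saturates regardless of stiffness
      stop(sprintf(
        "no wall area in [%.4g, %.4g] mm^2 restores the %.3g kPa set-point at %.1f%% constriction (achievable stress range: %.4g to %.4g kPa); the held stretch %.3f is at or below the tension threshold %.3f",
        A0, max_growth * A0, spec$sigma_setpoint, 100 * constriction,
        sigma_held(A0), sigma_held(max_growth * A0),
        kin_c$lambda_theta, 1 / sqrt(lz)))
    }
    f_hi <- f(hi)
  }
  A_star <- if (hi == A0) A0
            else stats::uniroot(f, c(hi / 1.3, hi), tol = 1e-10)$root
  m_star <- material_at(A_star)
  ref_star <- airway_geometry(r_in0, sqrt(r_in0^2 + lz * A_star / pi))
  c1 <- specific_compliance(ref_star, lz, m_star, 0, spec$p_tlc)
  structure(list(constriction = constriction,
                 wall_area = A_star,
                 params = m_star,
                 sigma_restored = sigma_held(A_star),
                 d_wall_area = (A_star - A0) / A0,
                 d_compliance = (c1 - c0) / c0,
                 baseline = list(wall_area = A0, compliance = c0,
                                 R_operating = R_op,
                                 generation = airway$generation)),
            class = "remodeling_result")
}

#' @export
print.remodeling_result <- function(x, ...) {
  cat(sprintf(
    "Remodeling at %.0f%% chronic constriction (generation %s): wall area %+.1f%%, passive specific compliance %+.1f%% (sigma_theta restored to %.4g kPa)\n",
    100 * x$constriction, x$baseline$generation, 100 * x$d_wall_area,
    100 * x$d_compliance, x$sigma_restored))
  invisible(x)
}
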