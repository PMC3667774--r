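# Constitutive parameter estimation from a pressure-radius curve by
# deterministic grid search with shrink-and-refine rounds.

#' Grid-search specification
#'
#' Defines the log-spaced search grid for the deterministic estimation of
#' the constitutive parameters. Refinement rounds shrink each axis by
#' `shrink` (in log space) about the incumbent and re-grid with an odd
#' point count so the incumbent stays on the grid; refined windows are
#' clipped to the original bounds.
#'
#' @param lower,upper Named positive numeric vectors of axis bounds, e.g.
#'   `c(k1 = 0.5, k2 = 0.01, k3 = 0.5)`.
#' @param n Points per axis (>= 2).
#' @param refine Number of refinement rounds.
#' @param shrink Per-round shrink factor of each axis span.
#' @return An object of class `"grid_spec"`.
#' @export
grid_spec <- function(lower = c(k1 = 0.5, k2 = 0.01, k3 = 0.5),
                      upper = c(k1 = 50, k2 = 5, k3 = 300),
                      n = 20L, refine = 2L, shrink = 5) {
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == length(upper),
            identical(names(lower), names(upper)))
  if (any(lower <= 0) || any(upper <= lower))
    stop("grid bounds must satisfy 0 < lower < upper on every axis")
  if (n < 2L) stop("'n' must be >= 2")
  if (refine < 0L) stop("'refine' must be >= 0")
  if (shrink <= 1) stop("'shrink' must be > 1")
  structure(list(lower = lower, upper = upper, n = as.integer(n),
                 refine = as.integer(refine), shrink = shrink),
            class = "grid_spec")
}

# Exhaustive log-spaced grid search with shrink-and-refine, deterministic,
# lexicographic tie-break on the parameter vector. `objective` takes a
# named numeric vector (one value per axis) and returns a scalar (may be
# Inf on failure).
.grid_search <- function(objective, grid) {
  lo0 <- log(grid$lower); hi0 <- log(grid$upper)
  axes_names <- names(grid$lower)
  best_par <- NULL; best_val <- Inf
  n_eval <- 0L; n_fail <- 0L
  lo <- lo0; hi <- hi0

  for (round in 0:grid$refine) {
    n_pts <- if (round == 0L) grid$n else grid$n + (grid$n %% 2L == 0L)
    axes <- lapply(seq_along(lo), function(a)
      if (lo[a] == hi[a]) lo[a] else seq(lo[a], hi[a], length.out = n_pts))
    pts <- as.matrix(expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE))
    # expand.grid over reversed axes + reversal of columns => row order is
    # lexicographic in (axis1, axis2, ...), so the first minimum found is
    # the lexicographically smallest: deterministic tie-breaking.
    pts <- pts[, rev(seq_len(ncol(pts))), drop = FALSE]
    colnames(pts) <- axes_names
    for (i in seq_len(nrow(pts))) {
      par <- exp(pts[i, ])
      val <- tryCatch(objective(par), error = function(e) Inf)
      n_eval <- n_eval + 1L
      if (!is.finite(val)) { n_fail <- n_fail + 1L; val <- Inf }
      if (val < best_val) { best_val <- val; best_par <- par }
    }
    if (is.null(best_par))
      stop("grid search failed: the objective could not be evaluated ",
           "anywhere on the grid")
    centre <- log(best_par)
    span <- (hi - lo) / (2 * grid$shrink)
    lo <- pmax(centre - span, lo0)
    hi <- pmin(centre + span, hi0)
  }
  boundary <- any(abs(log(best_par) - lo0) < 1e-12 |
                  abs(log(best_par) - hi0) < 1e-12)
  list(par = best_par, value = best_val, n_eval = n_eval,
       n_fail = n_fail, boundary = boundary)
}

#' Fit airway wall material parameters to a pressure-radius curve
#'
#' Estimates the constitutive triplet (`k1`, `k2`, `k3`) of the
#' strain-energy function by exhaustive log-spaced grid search (with
#' shrink-and-refine rounds) minimising the sum of squared errors between
#' the measured transmural pressures and the model pressure
#' [luminal_pressure()] evaluated at the measured inner radii. Only
#' records with `p_tm >= 0` are used (the expiratory positive branch);
#' negative-pressure records are dropped with a message. The reference
#' geometry is inferred from the zero-pressure record via
#' [extract_reference_geometry()].
#'
#' @param curve A [pressure_radius_curve()] with at least 5 non-negative
#'   pressure records and a zero-pressure record carrying `r_out`.
#' @param grid A [grid_spec()] with axes `k1`, `k2`, `k3`.
#' @param lambda_z Axial stretch during acquisition; defaults to the
#'   curve's `lambda_z` attribute.
#' @return An object of class `"airway_fit"` with elements `params`
#'   ([airway_material()]), `sse` (kPa^2), `rmse` (kPa), `ref`
#'   ([airway_geometry()]), `lambda_z`, `curve` (the retained records) and
#'   `diagnostics` (evaluations, failures, boundary flag, dropped record
#'   count). Supports `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot` and `simulate`.
#' @examples
#' truth <- airway_material(4, 0.6, 24)
#' ref <- airway_geometry(1, 1.12)
#' cfg <- synth_curve_config(truth, ref, lambda_z = 1.2, noise_sd = 0)
#' fit <- airway_fit(synth_pressure_radius(cfg),
#'                   grid = grid_spec(n = 8, refine = 1))
#' coef(fit)
#' @export
airway_fit <- function(curve, grid = grid_spec(), lambda_z = NULL) {
  stopifnot(inherits(curve, "pressure_radius_curve"),
            inherits(grid, "grid_spec"))
  if (!identical(names(grid$lower), c("k1", "k2", "k3")))
    stop("'grid' must have axes k1, k2, k3")
  if (is.null(lambda_z)) lambda_z <- attr(curve, "lambda_z")

  ref <- extract_reference_geometry(curve)
  n_neg <- sum(curve$p_tm < 0)
  if (n_neg > 0) {
    message(sprintf("dropping %d negative-pressure record(s); %s",
                    n_neg, "only the p_tm >= 0 branch is modelled"))
    curve <- curve[curve$p_tm >= 0, , drop = FALSE]
  }
  if (nrow(curve) < 5L)
    stop("need at least 5 records with p_tm >= 0 to fit")
  ord <- order(curve$p_tm)           # record-order invariance
  p_meas <- curve$p_tm[ord]
  R_meas <- curve$r_in[ord]

  # Precompute, per record, the Gauss-Legendre coefficients of the
  # pressure integral so the grid objective reduces to one evaluation of
  # dW/dI1 on a records x nodes matrix (identical to luminal_pressure on
  # the same rule; asserted in the test suite).
  rule <- .gl_rule(64L)
  half <- (ref$r_out - ref$r_in) / 2
  r_nodes <- (ref$r_out + ref$r_in) / 2 + half * rule$x
  w_nodes <- half * rule$w
  lz2 <- lambda_z^2
  R2 <- outer(R_meas^2, (r_nodes^2 - ref$r_in^2) / lambda_z, `+`)
  lt2 <- sweep(R2, 2, r_nodes^2, `/`)
  lr2 <- 1 / (lt2 * lz2)
  I1 <- lt2 + lr2 + lz2
  coefm <- sweep(2 * (lt2 - lr2) / (lambda_z * R2), 2,
                 w_nodes * r_nodes, `*`)

  objective <- function(par) {
    m <- airway_material(par[["k1"]], par[["k2"]], par[["k3"]])
    p_model <- rowSums(coefm * sedf_prime(I1, m))
    sum((p_meas - p_model)^2)
  }

  res <- .grid_search(objective, grid)
  if (res$boundary)
    warning("best-fitting parameters lie on the grid boundary; ",
            "consider widening the grid")
  params <- airway_material(res$par[["k1"]], res$par[["k2"]],
                            res$par[["k3"]])
  structure(list(
    params = params,
    sse = res$value,
    rmse = sqrt(res$value / length(p_meas)),
    ref = ref,
    lambda_z = lambda_z,
    curve = pressure_radius_curve(p_meas, R_meas,
                                  curve$r_out[ord], lambda_z,
                                  attr(curve, "label")),
    diagnostics = list(n_eval = res$n_eval, n_fail = res$n_fail,
                       boundary = res$boundary, dropped_negative = n_neg,
                       grid = grid),
    call = match.call()),
    class = "airway_fit")
}

#' @export
print.airway_fit <- function(x, ...) {
  cat("Hyperelastic airway wall fit\n")
  cat(sprintf("  curve: '%s' (%d records), lambda_z = %.3g\n",
              attr(x$curve, "label"), nrow(x$curve), x$lambda_z))
  cat(sprintf("  k1 = %.4g kPa, k2 = %.4g, k3 = %.4g kPa\n",
              x$params$k1, x$params$k2, x$params$k3))
  cat(sprintf("  pressure RMSE = %.4g kPa (%d grid evaluations)\n",
              x$rmse, x$diagnostics$n_eval))
  invisible(x)
}

#' @export
coef.airway_fit <- function(object, ...) {
  c(k1 = object$params$k1, k2 = object$params$k2, k3 = object$params$k3)
}

#' @export
fitted.airway_fit <- function(object, ...) {
  vapply(object$curve$r_in, luminal_pressure, numeric(1),
         ref = object$ref, lambda_z = object$lambda_z,
         material = object$params, method = "gauss")
}

#' @export
residuals.airway_fit <- function(object, ...) {
  object$curve$p_tm - fitted(object)
}

#' @export
summary.airway_fit <- function(object, ...) {
  res <- residuals(object)
  out <- list(fit = object,
              residual_range = range(res),
              compliance = specific_compliance(object$ref, object$lambda_z,
                                               object$params),
              yinc_op = incremental_modulus(0.75, object$ref,
                                            object$lambda_z, object$params),
              sigma_op = {
                st <- solve_deformed_state(0.75, object$ref,
                                           object$lambda_z, object$params)
                circumferential_stress_inner(st, object$ref, object$params)
              })
  class(out) <- "summary.airway_fit"
  out
}

#' @export
print.summary.airway_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual range: [%.4g, %.4g] kPa\n",
              x$residual_range[1], x$residual_range[2]))
  cat(sprintf("  specific compliance (0-3 kPa): %.4g 1/kPa\n", x$compliance))
  cat(sprintf("  at 0.75 kPa: sigma_theta(inner) = %.4g kPa, Y_inc = %.4g kPa\n",
              x$sigma_op, x$yinc_op))
  invisible(x)
}

#' Predict radii or pressures from a fitted airway model
#'
#' @param object An [airway_fit()].
#' @param p_tm Pressures (kPa) at which to predict inner radii
#'   (`type = "radius"`).
#' @param r_in Inner radii (mm) at which to predict pressures
#'   (`type = "pressure"`).
#' @param type `"radius"` or `"pressure"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.airway_fit <- function(object, p_tm = NULL, r_in = NULL,
                               type = c("radius", "pressure"), ...) {
  type <- match.arg(type)
  if (type == "radius") {
    if (is.null(p_tm)) p_tm <- object$curve$p_tm
    vapply(p_tm, function(p)
      solve_deformed_state(p, object$ref, object$lambda_z,
                           object$params)$R_in, numeric(1))
  } else {
    if (is.null(r_in)) r_in <- object$curve$r_in
    vapply(r_in, luminal_pressure, numeric(1), ref = object$ref,
           lambda_z = object$lambda_z, material = object$params,
           method = "gauss")
  }
}

#' @export
plot.airway_fit <- function(x, n_grid = 61L, ...) {
  p_grid <- seq(min(x$curve$p_tm), max(x$curve$p_tm), length.out = n_grid)
  R_grid <- predict(x, p_tm = p_grid)
  graphics::plot(x$curve$p_tm, x$curve$r_in,
                 xlab = "Transmural pressure (kPa)",
                 ylab = "Inner radius (mm)", col = "red", ...)
  graphics::lines(p_grid, R_grid)
  graphics::legend("bottomright", legend = c("data", "model"),
                   col = c("red", "black"), pch = c(1, NA),
                   lty = c(NA, 1), bty = "n")
  invisible(x)
}

#' Simulate noisy pressure-radius curves from a fitted model
#'
#' @param object An [airway_fit()].
#' @param nsim Number of curves.
#' @param seed Integer seed (required for reproducibility).
#' @param noise_sd Relative radius noise standard deviation.
#' @param ... Unused.
#' @return A list of [pressure_radius_curve()] objects.
#' @export
simulate.airway_fit <- function(object, nsim = 1, seed = 1,
                                noise_sd = 0.005, ...) {
  p <- sort(object$curve$p_tm, decreasing = TRUE)
  lapply(seq_len(nsim), function(i) {
    cfg <- synth_curve_config(object$params, object$ref,
                              lambda_z = object$lambda_z,
                              p_start = max(p), p_stop = min(p),
                              p_step = if (length(p) > 1)
                                abs(stats::median(diff(p))) else 0.1,
                              noise_sd = noise_sd, seed = seed + i - 1L)
    synth_pressure_radius(cfg)
  })
}
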