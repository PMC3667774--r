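# Seeded synthetic-data generation: pressure-radius ramps with
# ultrasound-like radius noise, and per-generation airway dimension tables
# with the exponential radius decay and shared linear wall-area-radius
# relation the tree analysis assumes.

# run code under a local RNG seed without disturbing global RNG state
.with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  fn()
}

#' Synthetic pressure-radius curve configuration
#'
#' Describes a simulated quasi-static expiratory pressure ramp: the true
#' material and geometry, the acquisition axial stretch, the pressure
#' grid (stored high-to-low, the expiratory limb), multiplicative
#' Gaussian radius noise (the imaged quantity; pressure is controlled) and
#' a seed.
#'
#' @param params True [airway_material()].
#' @param ref True [airway_geometry()].
#' @param lambda_z Axial stretch during acquisition (default 1.2, the
#'   physiological pre-stretch).
#' @param p_start,p_stop,p_step Pressure grid in kPa; `p_start > p_stop`,
#'   step > 0.
#' @param noise_sd Relative standard deviation of the radius noise
#'   (default 0.5%, a nominal sub-pixel imaging precision; 0 = noiseless).
#' @param seed Integer seed.
#' @param label Curve label.
#' @return An object of class `"synth_curve_config"`.
#' @export
synth_curve_config <- function(params, ref, lambda_z = 1.2,
                               p_start = 3, p_stop = 0, p_step = 0.1,
                               noise_sd = 0.005, seed = 1L,
                               label = "synthetic") {
  stopifnot(inherits(params, "airway_material"),
            inherits(ref, "airway_geometry"),
            p_step > 0, p_start > p_stop, p_stop >= 0, noise_sd >= 0)
  structure(list(params = params, ref = ref, lambda_z = lambda_z,
                 p_start = p_start, p_stop = p_stop, p_step = p_step,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 label = label),
            class = "synth_curve_config")
}

#' Generate a synthetic pressure-radius curve
#'
#' Exact forward solution of the inflation model on the configured
#' pressure grid, with seeded multiplicative Gaussian noise applied to
#' both radii. Noiseless output round-trips through [airway_fit()] to the
#' generating parameters.
#'
#' @param cfg A [synth_curve_config()].
#' @return A [pressure_radius_curve()] (expiratory order, high to low
#'   pressure).
#' @export
synth_pressure_radius <- function(cfg) {
  stopifnot(inherits(cfg, "synth_curve_config"))
  p <- seq(cfg$p_start, cfg$p_stop, by = -cfg$p_step)
  states <- lapply(p, function(pp)
    solve_deformed_state(pp, cfg$ref, cfg$lambda_z, cfg$params))
  R_in <- vapply(states, `[[`, numeric(1), "R_in")
  R_out <- vapply(states, `[[`, numeric(1), "R_out")
  if (cfg$noise_sd > 0) {
    noise <- .with_seed(cfg$seed, function()
      matrix(stats::rnorm(2 * length(p), 0, cfg$noise_sd), ncol = 2))
    R_in <- R_in * (1 + noise[, 1])
    R_out <- R_out * (1 + noise[, 2])
  }
  pressure_radius_curve(p, R_in, R_out, lambda_z = cfg$lambda_z,
                        label = cfg$label)
}

#' Synthetic airway-tree configuration
#'
#' Defaults emulate an adult conducting tree: tracheal TLC radius 9 mm
#' decaying by a factor 0.79 per generation over 15 generations, and the
#' shared linear wall-area-radius line `A_w = 7.2 * R + 0.3` (slope mm,
#' intercept mm^2), which puts the tracheal wall-thickness-to-radius ratio
#' at TLC near 0.12 with peripherally increasing relative thickness.
#' Newborn and child trees scale the radii by their age factors and read
#' wall areas off the same line.
#'
#' @param generations Number of generations (0-indexed).
#' @param R0 Tracheal (generation 0) TLC radius in mm.
#' @param decay Per-generation radius decay factor, in (0, 1).
#' @param aw_slope,aw_intercept Wall-area line coefficients (mm, mm^2).
#' @param age_factors Named radius scale factors per age group.
#' @param seed Integer seed (the tables themselves are deterministic; the
#'   seed is carried for bundle provenance).
#' @return An object of class `"synth_tree_config"`.
#' @export
synth_tree_config <- function(generations = 15L, R0 = 9, decay = 0.79,
                              aw_slope = 7.2, aw_intercept = 0.3,
                              age_factors = c(newborn = 0.3, child = 0.5,
                                              adult = 1),
                              seed = 1L) {
  stopifnot(generations >= 1, R0 > 0, decay > 0, decay < 1, aw_slope > 0,
            aw_intercept >= 0, all(age_factors > 0))
  structure(list(generations = as.integer(generations), R0 = R0,
                 decay = decay, aw_slope = aw_slope,
                 aw_intercept = aw_intercept, age_factors = age_factors,
                 seed = as.integer(seed)),
            class = "synth_tree_config")
}

#' Generate synthetic airway dimension tables
#'
#' One [airway_dimension_table()] per age group: adult radii
#' `R(g) = R0 * decay^g`, younger ages scaled by their age factor, wall
#' areas read off the shared line for every age (same radius, same wall
#' area, regardless of age).
#'
#' @param cfg A [synth_tree_config()].
#' @param age_groups Which tables to produce (default all configured).
#' @return Named list of [airway_dimension_table()] objects.
#' @export
synth_tree_table <- function(cfg = synth_tree_config(),
                             age_groups = names(cfg$age_factors)) {
  stopifnot(inherits(cfg, "synth_tree_config"))
  g <- 0:(cfg$generations - 1L)
  out <- lapply(age_groups, function(ag) {
    R <- cfg$R0 * cfg$decay^g * cfg$age_factors[[ag]]
    A <- cfg$aw_slope * R + cfg$aw_intercept
    thick <- sqrt(R^2 + A / pi) - R
    if (any(thick < 0.01 * R))
      stop("configured wall-area line gives a wall thinner than 1% of ",
           "the radius for age group '", ag, "'")
    airway_dimension_table(g, R, A, ag)
  })
  names(out) <- age_groups
  out
}

#' Generate the shared incremental-modulus reference curve
#'
#' Builds the homeostasis condition-(1) curve by solving, for a nominal
#' mid-range airway (default: generation 7 of the default synthetic adult
#' tree), the two-parameter problem `sigma_theta(p_operating) =
#' sigma_target` and `Y_inc(p_operating) = yinc_target` with
#' `k3 = k3_over_k1 * k1`, then tabulating that airway's incremental
#' modulus over a pressure grid. The packaged default fixture
#' (`extdata/yinc_reference_synthetic.csv`) was produced by this function
#' with its defaults; it is synthetic, standing in for a population mean
#' modulus-pressure curve.
#'
#' @param r_in_tlc,wall_area_tlc Nominal airway TLC dimensions (mm, mm^2).
#' @param sigma_target Inner-wall stress target at `p_operating` (kPa).
#' @param yinc_target Incremental modulus target at `p_operating` (kPa).
#' @param p_operating Operating pressure (kPa).
#' @param pressures Tabulation grid (kPa).
#' @param k3_over_k1 Stiffness ratio constraint.
#' @param lambda_z Axial pre-stretch.
#' @param p_tlc TLC pressure (kPa).
#' @return List with `curve` (data frame `p_tm_kpa`, `yinc_kpa`) and
#'   `params` (the solved [airway_material()]).
#' @export
make_yinc_reference <- function(r_in_tlc = 9 * 0.79^7,
                                wall_area_tlc = 7.2 * 9 * 0.79^7 + 0.3,
                                sigma_target = 12, yinc_target = 245,
                                p_operating = 0.75,
                                pressures = seq(0.25, 3, by = 0.05),
                                k3_over_k1 = 6, lambda_z = 1.2,
                                p_tlc = 3) {
  record <- list(generation = NA_integer_, r_in_tlc = r_in_tlc,
                 wall_area_tlc = wall_area_tlc)
  # minimal spec carrier for reference_from_tlc (the reference curve slot
  # is irrelevant here)
  spec <- homeostasis_spec(
    sigma_setpoint = sigma_target, p_operating = p_operating,
    yinc_reference = data.frame(p_tm_kpa = range(pressures),
                                yinc_kpa = c(1, 2)),
    k3_over_k1 = k3_over_k1, lambda_z = lambda_z, p_tlc = p_tlc,
    yinc_pressures = range(pressures))

  at <- function(k1, k2) {
    m <- airway_material(k1, k2, k3_over_k1 * k1)
    ref <- reference_from_tlc(record, m, spec)
    st <- solve_deformed_state(p_operating, ref, lambda_z, m)
    list(m = m, ref = ref,
         sigma = circumferential_stress_inner(st, ref, m),
         yinc = incremental_modulus(p_operating, ref, lambda_z, m))
  }
  k1_for_sigma <- function(k2) {
    f <- function(lk1) at(exp(lk1), k2)$sigma - sigma_target
    exp(stats::uniroot(f, c(log(1e-3), log(1e3)), tol = 1e-12)$root)
  }
  g <- function(lk2) {
    k2 <- exp(lk2)
    at(k1_for_sigma(k2), k2)$yinc - yinc_target
  }
  k2 <- exp(stats::uniroot(g, c(log(0.05), log(100)), tol = 1e-12)$root)
  sol <- at(k1_for_sigma(k2), k2)
  yinc <- .yinc_curve(pressures, sol$ref, lambda_z, sol$m)
  list(curve = data.frame(p_tm_kpa = pressures,
                          yinc_kpa = round(yinc, 6)),
       params = sol$m)
}

#' Write a complete synthetic input bundle
#'
#' Produces, under `dir`: 11 synthetic airway pressure-radius CSVs
#' (`curve_01.csv` ... `curve_11.csv`, emulating an 11-airway ex vivo
#' study) with geometry and material parameters drawn from seeded
#' physiological ranges; newborn/child/adult dimension tables
#' (`tree_<age>.csv`); the default modulus reference curve
#' (`yinc_reference.csv`); and a `manifest.json`. Byte-identical for a
#' fixed seed.
#'
#' @param dir Target directory (created if needed).
#' @param seed Integer seed.
#' @param n_curves Number of airway curves.
#' @param noise_sd Relative radius noise of the curves.
#' @return The manifest as a list, invisibly.
#' @export
make_fixture_bundle <- function(dir, seed = 1L, n_curves = 11L,
                                noise_sd = 0.005) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  draws <- .with_seed(seed, function() data.frame(
    r_in = stats::runif(n_curves, 1.2, 4),
    wall_ratio = stats::runif(n_curves, 0.1, 0.16),
    k1 = exp(stats::runif(n_curves, log(1.5), log(8))),
    k2 = exp(stats::runif(n_curves, log(0.3), log(2))),
    k3_mult = stats::runif(n_curves, 4, 8)))
  curve_files <- character(n_curves)
  for (i in seq_len(n_curves)) {
    d <- draws[i, ]
    params <- airway_material(d$k1, d$k2, d$k3_mult * d$k1)
    ref <- airway_geometry(d$r_in, d$r_in * (1 + d$wall_ratio))
    cfg <- synth_curve_config(params, ref, lambda_z = 1.2,
                              noise_sd = noise_sd, seed = seed + i,
                              label = sprintf("curve_%02d", i))
    curve_files[i] <- sprintf("curve_%02d.csv", i)
    write_pressure_radius_csv(synth_pressure_radius(cfg),
                              file.path(dir, curve_files[i]))
  }
  tables <- synth_tree_table(synth_tree_config(seed = seed))
  tree_files <- vapply(names(tables), function(ag) {
    f <- sprintf("tree_%s.csv", ag)
    write_dimension_csv(tables[[ag]], file.path(dir, f))
    f
  }, character(1))
  utils::write.csv(default_yinc_reference(),
                   file.path(dir, "yinc_reference.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(seed = seed, noise_sd = noise_sd,
                   curves = curve_files,
                   trees = unname(tree_files),
                   yinc_reference = "yinc_reference.csv",
                   true_params = draws)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
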