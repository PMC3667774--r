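test_that("stress difference vanishes at the undeformed state and matches a finite-difference oracle", {
  m <- test_material()
  expect_equal(stress_difference(kinematics_at(1, 1, 1), m), 0)
  # symmetric stretch state (lambda_theta = lambda_r) carries no difference
  lz <- 1.3
  lt <- 1 / sqrt(lz)
  expect_equal(stress_difference(kinematics_at(lt, 1, lz), m), 0,
               tolerance = 1e-12)
  # oracle: lambda_theta * d/dlambda_theta of W(lambda_theta; lambda_z
  # fixed, lambda_r from incompressibility), by central difference
  lt <- 1.3; lz <- 1.2; h <- 1e-6
  What <- function(lt) {
    lr <- 1 / (lt * lz)
    sedf(lt^2 + lr^2 + lz^2, m)
  }
  oracle <- lt * (What(lt + h) - What(lt - h)) / (2 * h)
  expect_equal(stress_difference(kinematics_at(lt, 1, lz), m), oracle,
               tolerance = 1e-6)
})

test_that("luminal pressure agrees with a dense trapezoid oracle and its Gauss kernel", {
  set.seed(7)
  for (i in 1:10) {
    r_in <- runif(1, 0.5, 4)
    ref <- airway_geometry(r_in, r_in * runif(1, 1.05, 1.4))
    lz <- runif(1, 1, 1.3)
    m <- airway_material(runif(1, 1, 10), runif(1, 0.1, 3),
                         runif(1, 1, 50))
    R_in <- ref$r_in / sqrt(lz) * runif(1, 1.01, 1.4)
    p_ad <- luminal_pressure(R_in, ref, lz, m)
    expect_equal(p_ad, trapezoid_pressure(R_in, ref, lz, m),
                 tolerance = 1e-6)
    expect_equal(p_ad, luminal_pressure(R_in, ref, lz, m, method = "gauss"),
                 tolerance = 1e-9)
  }
})

test_that("deformed-state solver is exact at zero pressure and inverts the pressure map", {
  m <- test_material(); ref <- test_geometry()
  st0 <- solve_deformed_state(0, ref, 1, m)
  expect_equal(st0$R_in, ref$r_in)
  expect_equal(st0$R_out, ref$r_out)
  expect_error(solve_deformed_state(-0.5, ref, 1.2, m), "negative")

  # pressure is strictly increasing in radius over the inflation range
  R <- seq(ref$r_in / sqrt(1.2), 1.6, length.out = 40)
  P <- vapply(R, luminal_pressure, numeric(1), ref = ref, lambda_z = 1.2,
              material = m, method = "gauss")
  expect_true(all(diff(P) > 0))

  # round trip across the 0-3 kPa sweep, and incompressibility of every
  # solved state
  for (p in seq(0, 3, by = 0.5)) {
    st <- solve_deformed_state(p, ref, 1.2, m)
    expect_equal(luminal_pressure(st$R_in, ref, 1.2, m, method = "gauss"),
                 p, tolerance = 1e-8)
    R_back <- solve_deformed_state(
      luminal_pressure(st$R_in, ref, 1.2, m, method = "gauss"),
      ref, 1.2, m)$R_in
    expect_equal(R_back, st$R_in, tolerance = 1e-8)
    expect_equal(1.2 * (st$R_out^2 - st$R_in^2),
                 ref$r_out^2 - ref$r_in^2, tolerance = 1e-9)
  }
})

test_that("wall stress profile satisfies both radial boundary conditions", {
  m <- test_material(); ref <- test_geometry()
  st <- solve_deformed_state(1.5, ref, 1.2, m)
  prof <- radial_stress_profile(st, ref, m, n_points = 41)
  expect_equal(prof$sigma_r[1], -1.5)
  expect_equal(prof$sigma_r[41], 0, tolerance = 1e-8)
  expect_equal(prof$sigma_theta[1],
               circumferential_stress_inner(st, ref, m))
  expect_error(radial_stress_profile(st, ref, m, n_points = 1), "n_points")

  # identity state: all stresses vanish everywhere
  st0 <- solve_deformed_state(0, ref, 1, m)
  prof0 <- radial_stress_profile(st0, ref, m, n_points = 11)
  expect_equal(max(abs(c(prof0$sigma_r, prof0$sigma_theta,
                         prof0$sigma_z))), 0, tolerance = 1e-10)
  expect_equal(circumferential_stress_inner(st0, ref, m), 0,
               tolerance = 1e-12)
})

test_that("thin-walled cylinder recovers LaPlace hoop stress within 1%", {
  m <- test_material()
  ref <- airway_geometry(1, 1.001)
  st <- solve_deformed_state(0.5, ref, 1, m)
  H <- st$R_out - st$R_in
  laplace <- 0.5 * st$R_in / H
  prof <- radial_stress_profile(st, ref, m, n_points = 3)
  expect_equal(prof$sigma_theta[2] / laplace, 1, tolerance = 0.01)
})

test_that("incremental modulus is positive, strain-stiffening and step-converged", {
  m <- test_material(); ref <- test_geometry()
  y <- vapply(seq(0.25, 3, by = 0.25), incremental_modulus, numeric(1),
              ref = ref, lambda_z = 1.2, material = m)
  expect_true(all(y > 0))
  expect_true(all(diff(y) > 0))
  y1 <- incremental_modulus(0.75, ref, 1.2, m, rel_step = 1e-4)
  y2 <- incremental_modulus(0.75, ref, 1.2, m, rel_step = 5e-5)
  expect_lt(abs(y2 / y1 - 1), 1e-3)
  # near-zero pressure the one-sided fallback still returns a positive slope
  expect_gt(incremental_modulus(0, ref, 1.2, m), 0)
})

test_that("specific compliance vanishes in the rigid limit and sits below the parenchymal benchmark formula", {
  ref <- test_geometry()
  soft <- specific_compliance(ref, 1.2, test_material())
  rigid <- specific_compliance(ref, 1.2, airway_material(4000, 0.6, 24000))
  expect_lt(rigid, soft / 100)
  # benchmark: isotropic expansion with 15% residual volume over 3 kPa
  expect_equal(parenchymal_hole_compliance(),
               ((1 / 0.15)^(1 / 3) - 1) / 3)
  expect_error(specific_compliance(ref, 1.2, test_material(),
                                   p_lo = 2, p_hi = 1), "p_lo")
})

test_that("breathing strain follows the radius-ratio formula", {
  m <- test_material(); ref <- test_geometry()
  expect_equal(strain_percent(1, 1, ref, 1.2, m), 0)
  R1 <- solve_deformed_state(0.5, ref, 1.2, m)$R_in
  R2 <- solve_deformed_state(3, ref, 1.2, m)$R_in
  expect_equal(strain_percent(0.5, 3, ref, 1.2, m),
               100 * (R2 - R1) / R1)
  # tidal window strain is smaller than the deep-inspiration window
  expect_lt(strain_percent(0.5, 1, ref, 1.2, m),
            strain_percent(0.5, 3, ref, 1.2, m))
})
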