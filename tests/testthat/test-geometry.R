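test_that("incompressible radial map honours its boundary identities", {
  ref <- airway_geometry(1, 1.2)
  # inner surface maps to the deformed inner radius
  expect_equal(deformed_radius_at(1, ref, R_in = 1.1, lambda_z = 1.2), 1.1)
  # identity deformation
  r <- seq(1, 1.2, by = 0.05)
  expect_equal(deformed_radius_at(r, ref, R_in = 1, lambda_z = 1), r)
  # against a numeric inversion of the volume-conservation relation
  R <- deformed_radius_at(1.2, ref, R_in = 1.1, lambda_z = 1.2)
  oracle <- uniroot(function(x) 1.2 * (x^2 - 1.1^2) - (1.2^2 - 1^2),
                    c(1.1, 2), tol = 1e-12)$root
  expect_equal(R, oracle, tolerance = 1e-9)
  expect_equal(R, 1.25566, tolerance = 1e-5)
  # monotone increasing in r
  expect_true(all(diff(deformed_radius_at(r, ref, 1.05, 1.2)) > 0))
  expect_error(deformed_radius_at(0.9, ref, 1.1, 1.2), "within")
})

test_that("kinematics satisfy incompressibility and the invariant formula", {
  k <- kinematics_at(R = 1, r = 1, lambda_z = 1)
  expect_equal(unlist(k[c("lambda_theta", "lambda_r", "lambda_z")]),
               c(lambda_theta = 1, lambda_r = 1, lambda_z = 1))
  expect_equal(k$I1, 3)

  k2 <- kinematics_at(R = 1.5, r = 1, lambda_z = 1.2)
  expect_equal(k2$lambda_r, 0.55556, tolerance = 1e-5)
  expect_equal(k2$I1, 3.99864, tolerance = 1e-5)

  # product of stretches is exactly 1 across random states
  set.seed(42)
  for (i in 1:25) {
    kk <- kinematics_at(runif(1, 0.5, 3), runif(1, 0.5, 3),
                        runif(1, 0.8, 1.5))
    expect_equal(kk$lambda_theta * kk$lambda_r * kk$lambda_z, 1,
                 tolerance = 1e-12)
    expect_gte(kk$I1, 3)
  }
})
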