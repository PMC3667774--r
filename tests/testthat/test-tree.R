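test_that("homeostasis spec validates its reference curve", {
  expect_error(homeostasis_spec(yinc_reference = data.frame(
    p_tm_kpa = c(0.25, 1, 3), yinc_kpa = c(100, 90, 300))), "monotone")
  expect_error(homeostasis_spec(yinc_pressures = c(0.1, 3)), "range")
  spec <- homeostasis_spec()
  expect_equal(spec$sigma_setpoint, 12)
  expect_equal(spec$p_operating, 0.75)
  expect_equal(spec$k3_over_k1, 6)
  expect_equal(spec$lambda_z, 1.2)
})

test_that("packaged modulus reference curve regenerates from its constructor", {
  res <- make_yinc_reference()
  expect_equal(res$curve, default_yinc_reference(), tolerance = 1e-6)
  # the nominal airway hits both targets by construction
  expect_true(all(diff(res$curve$yinc_kpa) > 0))
})

test_that("dimension reconstruction follows the decay law and the shared wall-area line", {
  co <- list(R0 = 9, decay_rate = -log(0.79), aw_slope = 7.2,
             aw_intercept = 0.3)
  adult <- reconstruct_dimensions("adult", co)
  expect_equal(nrow(adult), 15L)
  expect_equal(adult$r_in_tlc[1], 9)
  expect_true(all(diff(adult$r_in_tlc) < 0))
  expect_error(reconstruct_dimensions("adult", co[-1]), "missing")

  # shared-line property: a child airway with the same radius as an adult
  # airway has the same wall area
  tabs <- synth_tree_table(synth_tree_config())
  i <- 5
  r_child <- tabs$child$r_in_tlc[i]
  aw_line <- function(r) 7.2 * r + 0.3
  expect_equal(tabs$child$wall_area_tlc[i], aw_line(r_child))
  expect_equal(tabs$adult$wall_area_tlc[i],
               aw_line(tabs$adult$r_in_tlc[i]))
})

test_that("reference geometry from TLC dimensions round-trips and conserves wall volume", {
  spec <- homeostasis_spec()
  m <- airway_material(0.4, 7, 2.4)
  rec <- list(generation = 5L, r_in_tlc = 2.77, wall_area_tlc = 20.2)
  ref <- reference_from_tlc(rec, m, spec)
  st <- solve_deformed_state(spec$p_tlc, ref, spec$lambda_z, m)
  expect_equal(st$R_in, rec$r_in_tlc, tolerance = 1e-6)
  # reference wall area is lambda_z times the deformed wall area
  expect_equal(pi * (ref$r_out^2 - ref$r_in^2) / spec$lambda_z,
               rec$wall_area_tlc, tolerance = 1e-6)
  # near-rigid material: only the axial-thinning correction remains
  stiff <- airway_material(4000, 7, 24000)
  ref2 <- reference_from_tlc(rec, stiff, spec)
  expect_equal(ref2$r_in, rec$r_in_tlc * sqrt(spec$lambda_z),
               tolerance = 1e-3)
})

test_that("single-generation calibration hits the stress set-point under the ratio constraint", {
  spec <- homeostasis_spec()
  tbl <- default_tree_tables()$adult
  cal <- calibrate_generation(tbl[8, ], spec)
  expect_true(cal$converged)
  expect_lt(abs(cal$sigma_operating - spec$sigma_setpoint), 0.01)
  expect_identical(cal$params$k3, spec$k3_over_k1 * cal$params$k1)
  expect_gt(cal$yinc_operating, 180)
  expect_lt(cal$yinc_operating, 310)
})

test_that("tree calibration is deterministic and demands contiguous generations", {
  tbl <- default_tree_tables()$adult
  expect_error(calibrate_tree(tbl[c(1, 3, 5), ], homeostasis_spec()),
               "contiguous")
  expect_error(airway_dimension_table(c(0, 0), c(1, 1), c(1, 1)),
               "unique")
  # identical dimensions give identical parameters
  spec <- homeostasis_spec()
  two <- airway_dimension_table(0:1, rep(tbl$r_in_tlc[8], 2),
                                rep(tbl$wall_area_tlc[8], 2), "synthetic")
  tr <- calibrate_tree(two, spec)
  expect_identical(coef(tr)[1, ], coef(tr)[2, ])
})

test_that("calibrated default tree satisfies the homeostatic trends", {
  tree <- calibrated_default_tree()
  s <- summary(tree)
  expect_true(all(s$converged))
  # ground-state stiffness decreases from the trachea to the periphery
  expect_true(all(diff(s$k1) < 0))
  pr <- predict(tree)
  expect_true(all(vapply(split(pr$curves$lambda_theta,
                               pr$curves$generation),
                         function(l) all(diff(l) > 0), logical(1))))
})
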