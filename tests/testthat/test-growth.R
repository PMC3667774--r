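# minimal hand-built calibrated tree with a planted k1 = alpha * A_w law
planted_tree <- function(alpha = 0.02, n = 8) {
  aw <- seq(5, 40, length.out = n)
  airways <- lapply(seq_len(n), function(i) {
    structure(list(generation = i - 1L,
                   params = airway_material(alpha * aw[i], 2,
                                            6 * alpha * aw[i]),
                   record = list(r_in_tlc = 1, wall_area_tlc = aw[i]),
                   converged = TRUE),
              class = "calibrated_airway")
  })
  structure(list(airways = airways, spec = homeostasis_spec()),
            class = "airway_tree")
}

test_that("growth law recovers a planted proportional relation", {
  law <- fit_growth_law(planted_tree(alpha = 0.02))
  expect_equal(unname(law$coef_k1[2]), 1, tolerance = 1e-9)
  expect_equal(exp(unname(law$coef_k1[1])), 0.02, tolerance = 1e-9)
  # interpolation reproduces a fitted point
  m <- predict(law, 20)
  expect_equal(m$k1, 0.02 * 20, tolerance = 1e-9)
  expect_equal(m$k3, 6 * m$k1)
})

test_that("growth-law queries outside the range warn, and clamp when asked", {
  law <- fit_growth_law(planted_tree())
  expect_warning(m_ex <- predict(law, 80), "outside")
  expect_equal(m_ex$k1, 0.02 * 80, tolerance = 1e-9)
  expect_warning(m_cl <- predict(law, 80, rule = "clamp"), "clamped")
  expect_equal(m_cl$k1, 0.02 * 40, tolerance = 1e-9)
  expect_error(fit_growth_law(planted_tree(n = 4)), "at least 5")
})

test_that("growth trajectories are newborn-normalized and stiffen toward adulthood", {
  tree <- calibrated_default_tree()
  law <- fit_growth_law(tree)
  tabs <- default_tree_tables()
  spec <- homeostasis_spec()
  for (g in c(0L, 7L, 14L)) {
    tr <- suppressWarnings(growth_trajectory(g, tabs, law, spec))
    expect_equal(tr$normalized[tr$stage == "newborn"], 1)
    expect_lt(tr$normalized[tr$stage == "adult"],
              tr$normalized[tr$stage == "newborn"])
  }
  # identical dimensions across ages give a flat trajectory
  same <- list(newborn = tabs$adult, child = tabs$adult,
               adult = tabs$adult)
  flat <- suppressWarnings(growth_trajectory(3L, same, law, spec))
  expect_equal(flat$normalized, c(1, 1, 1))
  expect_error(growth_trajectory(99L, tabs, law, spec), "missing")
})

test_that("chronic constriction thickens and stiffens the wall, restoring the stress set-point", {
  tree <- calibrated_default_tree()
  law <- fit_growth_law(tree)
  spec <- homeostasis_spec()
  aw0 <- tree$airways[[1]]
  res <- chronic_constriction_remodel(aw0, 0.05, law, spec)
  expect_lt(abs(res$sigma_restored - spec$sigma_setpoint), 0.1)
  expect_gt(res$d_wall_area, 0)
  expect_lt(res$d_compliance, 0)
  # remodeled parameters sit on the anchored law
  expect_equal(res$params$k1,
               aw0$params$k1 *
                 (res$wall_area / res$baseline$wall_area)^law$coef_k1[[2]],
               tolerance = 1e-9)
  # vanishing constriction leaves the airway unchanged (continuity)
  tiny <- chronic_constriction_remodel(aw0, 1e-4, law, spec)
  expect_lt(abs(tiny$d_wall_area), 0.02)
  expect_lt(abs(tiny$d_compliance), 0.01)
  expect_error(chronic_constriction_remodel(aw0, 0.7, law, spec),
               "constriction")
  # beyond the tension threshold no stiffness restores the set-point
  expect_error(chronic_constriction_remodel(aw0, 0.5, law, spec),
               "achievable")
})
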