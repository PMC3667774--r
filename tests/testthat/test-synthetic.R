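test_that("synthetic curves are exact forward solutions with seeded noise", {
  truth <- test_material()
  ref <- airway_geometry(1.3, 1.5)
  # noiseless, unstretched, zero pressure: the record equals the reference
  cfg0 <- synth_curve_config(truth, ref, lambda_z = 1, noise_sd = 0,
                             p_start = 1, p_stop = 0, p_step = 0.5)
  cur0 <- synth_pressure_radius(cfg0)
  expect_equal(cur0$r_in[cur0$p_tm == 0], ref$r_in)
  expect_equal(cur0$r_out[cur0$p_tm == 0], ref$r_out)
  # every noiseless record satisfies the forward model
  for (i in seq_len(nrow(cur0)))
    expect_equal(luminal_pressure(cur0$r_in[i], ref, 1, truth,
                                  method = "gauss"),
                 cur0$p_tm[i], tolerance = 1e-8)

  # same seed, same curve; different seed, different curve
  cfg <- synth_curve_config(truth, ref, noise_sd = 0.005, seed = 11)
  expect_identical(synth_pressure_radius(cfg), synth_pressure_radius(cfg))
  cfg2 <- synth_curve_config(truth, ref, noise_sd = 0.005, seed = 12)
  expect_false(identical(synth_pressure_radius(cfg),
                         synth_pressure_radius(cfg2)))
  # the generator does not disturb global RNG state
  set.seed(99); before <- .Random.seed
  invisible(synth_pressure_radius(cfg))
  expect_identical(.Random.seed, before)
})

test_that("synthetic tree tables share one wall-area line across ages", {
  cfg <- synth_tree_config()
  tabs <- synth_tree_table(cfg)
  expect_named(tabs, c("newborn", "child", "adult"))
  expect_equal(tabs$adult$r_in_tlc[1], cfg$R0)
  for (tab in tabs) {
    expect_equal(nrow(tab), 15L)
    expect_true(all(diff(tab$r_in_tlc) < 0))
    expect_equal(tab$wall_area_tlc,
                 cfg$aw_slope * tab$r_in_tlc + cfg$aw_intercept)
  }
  # an implausibly thin wall is rejected
  thin <- synth_tree_config(aw_slope = 0.2, aw_intercept = 1e-4)
  expect_error(synth_tree_table(thin), "thinner")
})

test_that("fixture bundle is complete and byte-identical for a fixed seed", {
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- make_fixture_bundle(d1, seed = 5)
  m2 <- make_fixture_bundle(d2, seed = 5)
  expect_length(m1$curves, 11L)
  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  expect_true(all(c("curve_01.csv", "curve_11.csv", "tree_adult.csv",
                    "tree_newborn.csv", "tree_child.csv",
                    "yinc_reference.csv", "manifest.json") %in% files))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # curves re-read cleanly and carry the acquisition stretch
  cur <- read_pressure_radius_csv(file.path(d1, "curve_01.csv"))
  expect_equal(attr(cur, "lambda_z"), 1.2)
  expect_gte(min(cur$p_tm), 0)
  unlink(c(d1, d2), recursive = TRUE)
})
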