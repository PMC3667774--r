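# Shared fixtures, computed lazily and cached for the whole run.

.fixture_env <- new.env(parent = emptyenv())

# the default synthetic adult tree calibrated to the homeostasis spec
calibrated_default_tree <- function() {
  if (is.null(.fixture_env$tree)) {
    tbl <- synth_tree_table(synth_tree_config())$adult
    .fixture_env$tree <- calibrate_tree(tbl, homeostasis_spec())
  }
  .fixture_env$tree
}

default_tree_tables <- function() {
  if (is.null(.fixture_env$tables))
    .fixture_env$tables <- synth_tree_table(synth_tree_config())
  .fixture_env$tables
}

# a mid-sized test airway used across mechanics tests
test_material <- function() airway_material(k1 = 4, k2 = 0.6, k3 = 24)
test_geometry <- function() airway_geometry(r_in = 1, r_out = 1.12)

# independent quadrature oracle: dense composite trapezoid on the deformed
# radial coordinate of the equilibrium pressure integral
trapezoid_pressure <- function(R_in, ref, lambda_z, material,
                               n = 1e5) {
  R_out <- sqrt(R_in^2 + (ref$r_out^2 - ref$r_in^2) / lambda_z)
  R <- seq(R_in, R_out, length.out = n)
  r2 <- ref$r_in^2 + lambda_z * (R^2 - R_in^2)
  lt2 <- R^2 / r2
  lr2 <- 1 / (lt2 * lambda_z^2)
  I1 <- lt2 + lr2 + lambda_z^2
  f <- 2 * (lt2 - lr2) * sedf_prime(I1, material) / R
  sum((f[-1] + f[-n]) / 2 * diff(R))
}
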