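Package: airwaymech
Title: Hyperelastic Thick-Walled Mechanics of the Conducting Airway Tree
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Continuum-mechanics analysis of airway wall tissue as an
    incompressible, isotropic, hyperelastic thick-walled cylinder under
    plane strain. Provides forward and inverse transmural pressure-radius
    solvers built on a strain-energy density function, estimation of the
    constitutive parameters from quasi-static pressure-radius recordings by
    deterministic grid search, calibration of a whole conducting airway
    tree to mechanical-homeostasis set-points (fixed inner-wall
    circumferential stress and a shared incremental-modulus curve at the
    operating transmural pressure), and the derived predictions: specific
    airway compliance, breathing strains, growth trajectories from newborn
    to adult, and structural remodeling under chronic smooth-muscle
    constriction. Includes a seeded synthetic-data generator emulating the
    statistical structure of ultrasound pressure-radius ramps and
    CT-derived airway dimension tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    pracma,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
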