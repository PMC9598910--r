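Package: biaxdamage
Title: Damage-Coupled Anisotropic Hyperelasticity for Biaxial Soft-Tissue Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Layer-specific constitutive modelling of planar soft tissue
    (large-intestine wall) under equibiaxial tension. Implements a four-fiber
    Holzapfel-Gasser-Ogden strain-energy function with a neo-Hookean matrix,
    Kachanov-style scalar damage per collagenous layer with an exponential
    evolution law, analytic Cauchy stress, incompressible and penalty
    plane-stress protocol solvers (including a single-brick biaxial
    simulation), nonlinear least-squares parameter identification from
    stress-stretch curves, and a seeded synthetic biaxial-rig data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
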