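Package: oxyshear
Title: Shear-Induced Red Blood Cell Elongation Under Oxygenated and
    Deoxygenated Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale analysis chain from ektacytometry deformability
    curves of oxygenated and deoxygenated red blood cells to the spatial
    distribution of the elongation index (EI) in a vessel. Implements the
    EI definition from diffraction-pattern axes, Lineweaver-Burke
    parameterisation of EI-shear-stress curves (EImax, SS1/2), two-term
    exponential EI(SS) calibration functions with bounded multi-start
    nonlinear least squares, the Casson yield-stress shear-thinning
    blood viscosity model with hematocrit-dependent parameters, steady
    and pulsatile fully developed laminar flow solvers for channels and
    tubes with a semi-analytic Casson-Poiseuille oracle, wall shear
    stress extraction, mapping of shear-stress fields to EI fields, and
    a seeded synthetic generator of LORRCA-like deformability datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
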