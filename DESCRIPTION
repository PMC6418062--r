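Package: arfsim
Title: Stochastic Multiscale Simulation of Absolute Hip Fracture Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts a subject's current absolute risk of femoral fracture
    (ARF0) from fall biomechanics. A fall is idealised as an inverted
    pendulum whose kinetic energy, after postural-reflex attenuation, sets
    the hip impact velocity and peak impact force; flooring, hip-protector,
    active-muscle and trochanteric soft-tissue attenuation reduce the force
    transferred to the skeleton, which is compared against an
    orientation-dependent femoral strength surface to decide fracture of a
    single fall. Per-fall fracture probability is obtained by Latin-hypercube
    Monte Carlo integration over the fall parameters and triangular-grid
    quadrature over impact orientations, and converted to an annual risk via
    the binomial formula. The package includes the sampling machinery
    (truncated-normal inverse transforms, Latin-hypercube stratification,
    Iman-Conover rank-correlation induction), verification tools for the
    Monte Carlo and quadrature approximations, variance-based global
    sensitivity analysis with location-independent uncertainty bands,
    validation statistics (Mann-Whitney, Hosmer-Lemeshow, ROC/AUC with
    Youden-optimal thresholds) and a calibrated synthetic cohort generator
    with surrogate strength surfaces standing in for CT-based finite-element
    strength estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    nortest,
    lhs,
    optparse
Config/testthat/edition: 3
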