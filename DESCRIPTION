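Package: tbikin
Title: One-Compartment Kinetic Modeling of Blood Biomarkers After Mild
    Traumatic Brain Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse one-compartment (bi-exponential
    absorption-elimination) kinetic modeling of blood protein biomarkers
    (S100B, UCH-L1, tau, GFAP, NF-L) after mild traumatic brain injury.
    Provides the five published biomarker parameterizations, derivation of
    rate constants from half-life and time-of-peak, time-resolved partial
    correlation sensitivity analysis with a t-distribution significance
    band, Monte Carlo uncertainty propagation with mean-preserving
    lognormal input distributions, least-squares estimation of the amount
    of biomarker released at impact from sparse timed samples, and a
    synthetic-cohort generator with known ground truth for validating the
    estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
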