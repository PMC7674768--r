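Package: actichain
Title: Predictive Dosimetry and Xerostomia Risk Modelling for Ac-225
    PSMA Targeted Alpha Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predictive internal dosimetry of Ac-225 labelled
    PSMA radioligand therapy from Lu-177 surrogate kinetics. Implements
    triple-energy-window scatter correction and conjugate-view
    quantification of planar scintigraphy, exponential washout fitting
    and MIRD residence times, a unit-density sphere dose engine over the
    full Ac-225 decay chain with RBE weighting, the linear-quadratic
    biologically effective dose for a decaying mixture of radionuclides,
    EQD2 conversion, Lyman-Kutcher-Burman normal tissue complication
    probability for xerostomia, and cohort-level analysis with rescaling
    to a no-protector reference cohort. Ships the published 13-patient
    dose-coefficient and BED tables as fixtures and a synthetic-cohort
    generator with known kinetic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
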