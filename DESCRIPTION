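Package: bela
Title: Body Electrical Loss Analysis of Visceral Fat
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the body electrical loss analysis (BELA) pipeline for
    inductive assessment of visceral fat: the two-frequency loss-changing-rate
    statistic with its replicate-propagated repeatability, calibration of MRI
    visceral-fat areas on the loss rate (ordinary least squares with standard
    error of the estimate and leave-one-out cross-validation), correlation
    tables across abdominal levels and anthropometric covariates, a
    quasi-static layered-cylinder eddy-current forward model of the abdomen,
    and a seeded synthetic-cohort generator with an instrument noise budget
    (replicate, positioning and ADC quantization error) so the whole analysis
    is testable without clinical raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
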