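Package: bmissde
Title: Size-Specific Dose Estimates for Abdominal CT from Body Mass Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates size-specific dose (SSDE) for abdominal computed
    tomography from routinely available patient metrics. Implements body-size
    computations (BMI, effective diameter as the geometric mean of the
    anteroposterior and lateral skin-to-skin diameters, inner diameter and
    diameter ratio), an anthropometric regression predicting effective
    diameter from BMI, and an exponential CTDIvol-to-SSDE conversion-factor
    model calibrated by log-linear least squares to a packaged 36-row
    reference table for the 32-cm body phantom. A seeded synthetic-cohort
    generator emulates the distributional and correlation structure of an
    adult abdominal CT population so that the full validation analysis
    (correlations, regression refits, BMI-group contrasts) can be re-run
    without patient data. Includes cohort CSV input and output, JSON
    validation reports and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
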