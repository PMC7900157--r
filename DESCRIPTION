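Package: aortaflow
Title: Hemodynamic Quantification of Aortic Valve Prosthesis Flow Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies peak-systolic aortic hemodynamics downstream of a
    surgically implanted aortic valve prosthesis from steady voxel velocity
    fields, as produced by 4D flow MRI or computational fluid dynamics.
    Computes maximum jet velocity, the simplified-Bernoulli maximum pressure
    gradient, secondary flow degree and normalized flow displacement on
    standard aortic cross sections, effective orifice area and its
    body-surface-area index with patient-prosthesis-mismatch classification,
    prosthesis-orifice Reynolds numbers, Murray's-law outflow splits for the
    supra-aortic branches, and Carreau-Yasuda blood viscosity. Includes a
    synthetic-field generator with analytic ground truth (idealized aorta,
    eccentric swirling valve jet, MRI-like resampling and noise), streamline
    tracing, and the descriptive statistics used to compare paired MRI and
    CFD cohorts (ordinary least squares with R-squared and residual RMSE,
    median and interquartile range, prosthesis-size agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
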