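Package: nirscal
Title: Near-Infrared Reflectance Spectroscopy Calibration with Modified
    Partial Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete chemometrics workflow for calibrating near-infrared
    reflectance (NIRS) spectra against wet-chemistry reference values of
    forage constituents (moisture, crude protein, fiber fractions).
    Implements modified partial least squares (MPLS) regression with
    per-factor residual standardization and grouped cross-validation,
    WinISI-style math treatments (gap-segment derivatives with running-mean
    smoothing) and scatter corrections (SNV, detrend, standard and weighted
    MSC, mean-scaling with polynomial detrend), Mahalanobis (GH) spectral
    outlier screening in principal-component score space, iterative
    compositional outlier removal at a multiple of the cross-validation
    error, rank-stratified calibration/validation splitting, a pretreatment
    grid search, and the full calibration and validation statistics suite
    (SEC, SECV, RSQ, 1-VR, bias, SEP, SEP(C), slope, RPD) with model-quality
    classification bands. Includes a Beer-Lambert forward simulator of
    straw spectra so the whole pipeline can be exercised without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
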