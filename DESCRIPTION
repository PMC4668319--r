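Package: speccalib
Title: Multivariate UV Spectral Calibration with PLS1 and Linear Support
    Vector Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies a major analyte in the presence of spectrally
    overlapped minor impurities from full UV absorbance spectra. Implements
    PLS1 (NIPALS) multivariate calibration with bootstrap selection of the
    number of latent variables, and linear epsilon-insensitive support
    vector regression fitted by an exact two-coordinate dual solver with
    grid-searched k-fold cross-validation. Includes a multilevel multifactor
    calibration design builder, a Beer-Lambert spectral mixture simulator
    with Gaussian band models, figures of merit (RMSEC, RMSEP, recovery),
    and summary-statistic t- and F-tests for comparison against a reference
    method. Reads and writes delimited spectra/concentration tables and a
    JCAMP-DX subset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
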