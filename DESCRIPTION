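Package: vipboruta
Title: Wavelength Selection and Calibration Transfer for NIR Spectral
    Regression with VIP-Boruta
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building linear calibration models that predict
    metabolite concentrations (glucose, lactate) from near-infrared
    absorbance spectra of cell-culture media. Implements NIPALS partial
    least-squares regression with cross-validated latent-variable
    selection, the variable importance in projection (VIP) statistic,
    an all-relevant shadow-feature (Boruta-style) wavelength selector
    driven by either random-forest importance or PLS VIP, and a
    block-matrix transfer-learning design that pools culture-media and
    pseudo-media samples. Includes Savitzky-Golay derivative
    preprocessing, a Beer-Lambert synthetic spectra generator for
    batch-culture trajectories, and an end-to-end method comparison
    pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    signal,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    mixOmics,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
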