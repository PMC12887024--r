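Package: palmspec
Title: Machine-Learning Raman Calibration of Crude Palm Oil Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric workflow for simultaneous non-destructive prediction of
    peroxide value (PV, meq O2/kg) and iodine value (IV, g I2/100 g) of crude
    palm oil from Raman spectra (500-2000 cm-1, 1024 channels). Provides a
    seeded synthetic spectrum generator coupled to market-level PV/IV
    distributions, AOAC titration reference chemistry, spectral preprocessing
    (asymmetric least squares baseline correction, normalization,
    Savitzky-Golay smoothing and derivatives, wavelet denoising), wavelength
    selection by competitive adaptive reweighted sampling (CARS),
    uninformative variable elimination (UVE) and a genetic algorithm (GA) over
    a cross-validated SIMPLS engine, PLS / epsilon-SVR / random-forest
    calibration models behind a common fit/predict contract, Kennard-Stone
    partitioning, and RPD-based model evaluation orchestrated as the full
    12-model experiment grid.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    e1071,
    randomForest,
    Matrix,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
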