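Package: nircal
Title: NIR Calibration Workflow for Fruit Soluble Solids Content
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A chemometrics toolkit for building near-infrared (NIR)
    calibration models of fruit soluble solids content (SSC, degrees Brix).
    Implements spectral pretreatments (Savitzky-Golay smoothing,
    multiplicative scatter correction, standard normal variate, mean
    normalization) and ordered compositions of them, Kennard-Stone sample
    set partitioning, NIPALS partial least squares regression with
    RMSECV-driven latent-variable selection, and two wavelength selection
    algorithms: competitive adaptive reweighted sampling (CARS) and random
    frog.  A seeded synthetic FT-NIR spectra generator with known ground
    truth (informative wavelength windows, scatter parameters) makes the
    whole pipeline testable end to end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    signal,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
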