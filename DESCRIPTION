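Package: heatspec
Title: Growth-Stage Analysis of Canopy Hyperspectra Under Heat Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for analysing canopy reflectance spectra of
    reclamation vegetation under subsurface heat stress (e.g. above
    spontaneously combusting coal gangue). Covers spectral preprocessing
    (deduplication, resampling, Savitzky-Golay smoothing, first-derivative
    transformation), trilateral (three-edge) red-edge parameter extraction,
    exhaustive two-band vegetation-index optimisation, correlation- and
    successive-projections-algorithm (SPA) based band selection with
    RMSECV-driven subset sizing, and support vector / random forest / partial
    least squares regression of physiological indicators (SPAD chlorophyll,
    gas exchange, chlorophyll fluorescence). Includes a synthetic canopy
    spectra generator with the red edge, green peak and NIR plateau structure
    of herbaceous canopies so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    randomForest,
    mixOmics,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
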