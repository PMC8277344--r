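Package: gawkit
Title: Glottal Area Waveform Analysis for High-Speed Laryngoscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of high-speed videoendoscopy of
    the vocal folds. Implements seeded region growing segmentation of the
    glottal gap, anatomical-midline splitting into left and right glottal
    areas, extraction of normalized glottal-area and edge-length waveforms,
    FFT-based fundamental-frequency estimation with low-frequency motion
    rejection, and diagnostic parameters (amplitude asymmetry, closure
    deficit, lateral phase lag, frames per cycle) that separate common vocal
    pathologies. Also provides the chopper-wheel frame-rate calibration
    procedure for verifying a camera's true capture rate, and a
    ground-truthed synthetic vocal-fold video generator so that every stage
    of the pipeline can be validated without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
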