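Package: partseg
Title: Particle and Fiber Detection in Microscopy Images by Adaptive
    Thresholding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated detection and morphological characterization of
    particles and fibers in optical darkfield, fluorescence and scanning
    electron microscopy images, aimed at selecting measurement targets for
    single-point spectroscopy (e.g. Raman microspectroscopy of
    microplastics on filter substrates). Objects are segmented by a
    two-pass adaptive threshold with a Gaussian window (a large window for
    large objects, a small window for small ones), measured by the minimal
    enclosing rotated box (Feret diameters), classified as particle or
    fiber, and assigned a corrected measurement center that is guaranteed
    to lie inside the object material. The package also provides
    expert-annotation ground-truth extraction and TP/FP/FN scoring,
    exhaustive grid-search calibration of the five threshold
    hyperparameters against a consensus value, statistical subsampling of
    detections with a finite-population sample-size formula, image
    stitching, and a seeded synthetic scene generator with exact ground
    truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    mgcv,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
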