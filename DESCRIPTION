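Package: flagellaR
Title: Quantitative Analysis of Flagellar Beating from Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Reconstructs the flagellum of a single sperm cell in every frame
    of a calibrated grayscale time-lapse stack (dark-field or epifluorescence),
    refines the centerline to sub-pixel precision by fitting Gaussian profiles
    across the flagellum, and derives head kinematics (position, orientation
    angle, rolling intensity) and flagellar kinematics (head-frame coordinates,
    tangential angle, curvature, curvature angle, relative z-width, intensity)
    as a function of arc length and time. Includes FFT-based beat-frequency
    analysis (primary and secondary spectral peaks, spectrum center-of-mass,
    sliding windows), kymograph construction and CSV/plot export, and a
    synthetic dark-field movie renderer with exact analytic ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    igraph,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
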