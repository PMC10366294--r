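Package: capmech
Title: Mechanical Characterisation of Flowing Microcapsules from Steady
    Profiles in Tube Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the membrane constitutive-law class (neo-Hookean,
    Skalak or generalised 2D Hooke) and the membrane shear and
    area-dilatation moduli of a microcapsule flowing in a capillary tube,
    from a single camera-style image of its steady footprint profile.
    Provides the three classical membrane strain-energy laws and their
    modulus relations, a synthetic forward model that generates steady
    footprint profiles and rasterised images over a declared capillary
    number box, an image-processing chain (background subtraction,
    binarisation, border following, piecewise-quadratic smoothing and
    equal arc-length resampling) that converts an image into a
    boundary-coordinate feature vector, a small multilayer perceptron
    with a classification head for the law type and a regression head
    for the capillary numbers, and a mean-Hausdorff-distance inverse
    method that scans a labelled profile library as a baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
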