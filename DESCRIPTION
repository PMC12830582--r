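Package: dcshape
Title: Label-Free Deformability Cytometry Image Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis stack for brightfield deformability cytometry (DC)
    frame sequences. Detects and segments flowing objects by temporal-median
    background subtraction, Gaussian filtering, thresholding and
    morphological cleanup; extracts sub-pixel contours and computes the
    isoperimetric deformation statistic D = 1 - 2*sqrt(pi*A)/l together with
    projected area and related morphometric features; classifies event
    images into five classes (intact, anomalous, dead, aggregate, debris)
    with a convolutional neural network trained with inverse-frequency class
    weights, replacing manual gating; counts dark intracellular lipid
    droplet inclusions label-free; and aggregates per-sample summaries
    (class fractions, KDE-mode deformation and area, mean droplets per
    cell). Ships a synthetic frame generator with exact ground truth so the
    whole pipeline can be validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Matrix,
    EBImage,
    rhdf5,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
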