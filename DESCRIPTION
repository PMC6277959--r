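Package: platescan
Title: Plate-Scanning Microscopy: Stage Calibration, G-Code Planning,
    Z-Stack Segmentation and Focus Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Software toolkit for an open-hardware multi-well plate imager
    built on a CNC translation stage. Fits a bilinear (tensor-product
    linear) calibration surface from four manually measured corner-well
    coordinates and predicts the machine position of every well; emits the
    GRBL-dialect G-code program that rasters the plate, steps each well
    through a z-stack and pulses the camera relay with settle and
    file-write dwells; partitions the resulting numbered JPEG series into
    per-well z-stacks by detecting deliberately defocused sentinel images
    through their small compressed file size, tolerating occasional missing
    frames; and fuses each stack into a single extended-depth-of-field
    micrograph by translation alignment, local-contrast weighting and
    Laplacian-pyramid blending. A seeded synthetic-acquisition generator
    emulates defocus-dependent sharpness and JPEG size so the whole
    pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
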