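Package: aodmeter
Title: Automated Aortic Diameter Measurement from Axial CT Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for measuring the aortic diameter (AoD) on
    axial CT slices: a shallow-attention segmentation network with a Res2Net
    style multi-scale backbone, ellipse-based calibration of the predicted
    mask with a quality-rejection rule, conversion of the fitted minor axis
    to millimetres via pixel-spacing metadata, and subject-level ten-fold
    cross-validation reporting Dice and IoU with and without rejection.
    Includes a synthetic phantom generator producing CT-like slices with a
    single elliptical vessel of known geometry, so that every stage of the
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
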