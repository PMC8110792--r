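Package: gconequant
Title: Quantification of Axon Guidance and Growth Cone Dynamics in
    Neurosphere Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Image-based and track-based quantification of axon guidance
    assays performed on neurosphere cultures: quadrant-binned Sholl
    profiles and substratum-preference scores for stripe guidance assays,
    rule-based growth cone collapse classification from F-actin
    morphometrics, neurite outgrowth kinetics from time-lapse leading-edge
    tracks, acceptor-photobleaching FRET efficiency, G-LISA fold-activity
    normalization, and the associated group statistics. A seeded
    synthetic-data generator emulates every assay with known ground truth
    so each estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
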