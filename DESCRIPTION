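Package: declustr
Title: Quantitative 4D Image Analysis of Centromere De-Clustering in
    Drosophila Spermatocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for quantitative analysis of two-channel 4D
    fluorescence time-lapse movies of Drosophila spermatocytes during
    chromosome territory formation: diameter-parameterized 3D spot detection
    with subpixel localization, nuclear segmentation with
    distance-to-periphery geometry, motion-model particle tracking with
    drift correction and split/fusion lineage, per-cell dynamics metrics
    (dot-count stage durations with censoring, intensity ratios, pair
    separations, stretch episodes, radial positions), classification of
    centromere de-clustering programs and anaphase segregation ratios
    against a multinomial random-segregation null, and a ground-truthed
    synthetic movie generator that emulates the acquisitions so every
    estimator is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    clue,
    jsonlite,
    tiff,
    xml2,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
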