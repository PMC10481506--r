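Package: dentalabel
Title: FDI Tooth Numbering and Evaluation for Intra-Oral Scan Detections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing tools for tooth instance detections on 3D
    intra-oral scans: mesh reading/writing with instance annotations,
    bounding-box and point-sampling preprocessing, a three-stage
    combinatorial assignment algorithm that maps detected teeth to the 32
    FDI permanent-dentition codes using jaw side, left-right order and a
    distance-prior penalty, estimation of the inter-tooth distance prior
    from labeled scans, detection/segmentation/numbering evaluation
    metrics with per-tooth tables and confusion matrices, and a seeded
    synthetic dental-arch and detector-output simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
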