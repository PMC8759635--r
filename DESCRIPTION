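Package: flowseg
Title: Label-Free Cell Segmentation from Time-Lapse Microscopy via Dense Optical Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments living, unlabeled cells from time-lapse microscopy by the
    motion they generate between consecutive frames rather than by their intensity.
    Implements dense Farneback optical flow from scratch (per-pixel quadratic
    polynomial expansion solved coarse-to-fine over a resolution pyramid), a
    three-parameter segmentation chain (flow-magnitude threshold, morphological
    closing with hole filling, minimum-size filter), object-level F-score and
    pixel-level Jaccard evaluation against ground truth, and a seeded synthetic
    scene generator of textured deformable cells over flat or striped backgrounds
    so the whole pipeline is testable without external imagery. Includes a
    command-line interface for running, evaluating and simulating sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
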