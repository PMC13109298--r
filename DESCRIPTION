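Package: fieldpheno
Title: Automated Plot Delineation and Architectural Trait Phenotyping from
    UAS Orthomosaics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A fully automated pipeline for plot-level phenotyping of
    row-crop breeding trials from unmanned aerial system (UAS) imagery.
    Takes an RGB orthomosaic and a co-registered digital surface model,
    locates the experimental field and its orientation, segments individual
    two-row plots with a promptable-segmentation backend driven by
    automatically generated vegetation-index point prompts, reconstructs a
    digital terrain model by Delaunay interpolation of terrain points
    sampled beside each plot, and extracts canopy height, growth habit and
    mainstem prominence per plot. Includes a synthetic raised-bed field
    generator with full ground truth, the complete evaluation-metric suite
    (IoU, specificity/sensitivity/Dice, regression and classification
    metrics), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    tiff,
    jsonlite,
    foreign,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
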