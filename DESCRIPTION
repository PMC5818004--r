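Package: isletmorph
Title: Quantitative Image Analysis of Pancreatic Islet Morphogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify pancreatic islet morphogenesis in zebrafish
    larvae from volumetric fluorescence microscopy: automated 3D segmentation
    and volume quantitation of secondary islets, a convex-hull volume
    statistic over tracked endocrine cell centers, single-cell morphometry
    (area, circularity, solidity) and membrane-motility analysis, filopodial
    extension/retraction kinetics, and the group-comparison statistics used
    to compare treatment cohorts. Includes a synthetic-scene generator that
    renders ground-truthed image stacks, motion trajectories and filopodium
    length programs so the full pipeline can be exercised and validated
    without microscope data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    EBImage,
    igraph,
    clue,
    multcomp,
    tibble,
    dplyr,
    ggplot2,
    jsonlite,
    tiff,
    png,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
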