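Package: fociQuant
Title: Quantification of Fluorescent Foci, Colocalization and Per-Cell
    Statistics in High-Content Microscopy
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Per-cell analysis of multi-channel fluorescence microscopy
    fields from 96-well plates: Gaussian-blur watershed segmentation of
    adherent cells from a cytosolic channel, detection of bright punctae
    and foci by local intensity equalization with size and circularity
    filters, scoring of cells as foci-positive by in-cell foci pixel
    counts, marker colocalization of individual foci by a dilation-ring
    ("donut") intensity ratio, per-cell Pearson correlation between
    channels, and aggregation of per-cell values to per-image medians and
    per-well summaries. Includes a seeded synthetic microscopy scene
    simulator with per-cell and per-focus ground truth for validating
    every stage by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0)
biocViews: CellBiology, Visualization, Classification
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
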