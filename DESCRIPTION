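Package: brickplot
Title: Brick Plots: Two-Dimensional Barcode Visualization of Cytometry Cluster Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Renders the phenotype of high-dimensional cytometry cell clusters
    as "Brick plots": each protein marker is drawn as a square brick whose
    position reflects dataset-wide marker co-expression (principal component
    analysis of the marker correlation matrix, grouped by elbow-validated
    K-means) and whose area is proportional to the arcsinh-transformed median
    expression of that marker in that cluster. Sub-threshold markers are
    suppressed, overlapping bricks are deterministically displaced until
    interior-disjoint, and a single marker map is shared by every cluster of a
    dataset so plots are directly comparable. Includes CSV/TSV ingestion of
    cluster-by-marker median tables or per-event matrices, a seeded synthetic
    data generator with known co-expression block structure, SVG/PNG
    rendering, and a scripted end-to-end pipeline with JSON artifacts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
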