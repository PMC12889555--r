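Package: pixelpol
Title: Polarization and Colocalization Analysis of Pixel-Graph Surface Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of DNA pixel-based single-cell surface
    proteomics ("molecular pixelation") edge lists. Reconstructs bipartite
    pixel graphs from antibody binding events, calls cells by component edge
    count, derives marker count matrices and per-pixel tables, and scores
    spatial polarization (Moran's I z-scores on the pixel adjacency graph)
    and pairwise marker colocalization (Pearson correlation with a
    pixel-permutation null). Condition contrasts use Mann-Whitney U tests
    with Bonferroni correction, and cell-to-cell variability of polarization
    is tested with Gini-coefficient label-permutation and Monte-Carlo
    resampling nulls. Includes a synthetic edge-list generator with
    von Mises-Fisher surface hotspots so that every stage is testable with
    known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
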