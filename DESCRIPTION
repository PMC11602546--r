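Package: clonograph
Title: Clonality Inference on Cell-Adjacency Graphs from Multicolor Lineage Tracing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies clonal regeneration in multicolor (Rainbow/Confetti-style)
    lineage-tracing images of vascular networks. Converts per-color
    instance-segmentation label masks plus a vessel mask into cell-adjacency
    graphs by geodesic fast marching and marker watershed, measures local
    assortativity of color labels with personalized-PageRank locality weights,
    simulates clonal regeneration on each observed graph, and inverts the
    simulations with a per-graph mean-variance-estimation regressor to estimate
    the fraction of newly generated cells and the fraction of dividing
    progenitor cells, with logit-normal uncertainty, inverse-variance
    aggregation, and Bhattacharyya-distance posterior-predictive checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
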