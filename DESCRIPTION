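Package: rta
Title: Representational Topology Analysis of Dissimilarity Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Topological analysis of representational dissimilarity matrices
    (RDMs). Computes Vietoris-Rips persistent homology of an RDM by boundary
    matrix reduction over the field with two elements, including
    representative cycles for loops; exact bottleneck distances between
    persistence diagrams; bootstrap significance thresholding of diagrams;
    a paired-bootstrap permutation test with topological confidence
    intervals for adjudicating between candidate model RDMs; and
    proximity-labeled Rips graph (PLRG) visualizations that colour a Rips
    graph at the birth scale of a loop by classical multidimensional
    scaling coordinates. Seeded generators for point clouds with known
    topology (circle, annulus, torus, Gaussian clusters) support
    benchmarking against representational similarity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
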