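Package: connectoweave
Title: Connectome Matrix Conditioning, Sub-Network Selection, Graph Metrics
    and Connectogram Rendering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Scriptable analysis of parcel-based brain connectivity
    matrices. Reads and validates the three-file contract used by
    connectogram tools (an ordered atlas table, a label list, and a square
    symmetric non-negative weight matrix), supports seed-target exploration
    and induced-subgraph extraction of sub-networks, run-time density
    thresholding, weight normalisations and group consensus-matrix
    construction, computes a suite of binary and weighted local and global
    graph indices (including small-worldness against degree-preserving
    nulls, Louvain-style modularity, core-periphery coreness and rich-club
    curves) with reference-versus-case percent-delta reports, and renders
    circular connectograms whose edges are geodesic arcs of the Poincare
    hyperbolic disk, plus per-parcel local-index dot plots with top/bottom
    decile highlighting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    readxl,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    stats,
    grDevices
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
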