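Package: ppsnet
Title: Protein Family Classification with Similarity-Network Graph Pyramids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds protein-protein similarity (PPS) networks from pairwise
    alignment statistics by fusing E-values and bit-scores into a single
    nonnegative EB-score, models each protein family as a weighted undirected
    graph, and classifies query sequences by hierarchical voting over a graph
    pyramid: a ladder of edge-weight thresholds at which five graph-structured
    features (average clustering coefficient, rich-club coefficient, star-motif
    counts, triangle counts and graph energy) measure how a query perturbs each
    family graph. Includes an affine-gap local aligner so FASTA input can be
    scored without an external search tool, instance-based incremental
    learning, a synthetic benchmark generator with hub-dominated topology, and
    evaluation utilities (correct/wrong/no-decision accounting, precision, ROC
    sweeps, feature-evaluation efficiency) with ggplot2 graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
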