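Package: nafalign
Title: Network Alignment Frequency for Topology-Only Cross-Species
    Annotation Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ensembles of stochastically optimized, topology-only pairwise
    global alignments of protein-protein interaction networks.  Repeated
    co-alignment of a node pair across independently generated near-optimal
    alignments (its network alignment frequency, NAF) is used as a
    confidence score for functional similarity: the package computes NAF
    tables from simulated-annealing alignment ensembles, extracts common
    connected subgraphs at NAF thresholds, scores aligned protein pairs
    with max-variant Resnik semantic similarity over the Gene Ontology,
    and transfers GO terms across species with a time-split
    precision/recall evaluation framework.  Includes deterministic
    synthetic generators (noisy graph pairs with known correspondence and
    toy GO worlds) so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
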