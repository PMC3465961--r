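Package: odornet
Title: Topology, Divergence and Contribution in a Nematode Odor-Signaling Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating the topology of a gene-interaction network to
    molecular evolution and behavioral contribution, built around the
    16-gene volatile-odor signaling network of Caenorhabditis elegans.
    Implements pairwise codon-level divergence estimation (Nei-Gojobori 1986
    counting and the Yang-Nielsen 2000 approximate method), sliding-window
    nucleotide diversity, Cytoscape-style node topology metrics for simple
    undirected graphs, chemotaxis-derived phenotype and weighted phenotype
    indices, rank-correlation batteries, and a composition-constrained
    randomization null for network-mean dN/dS. A codon-model sequence
    simulator and graph/pool generators make every stage testable without
    external data; a curated reconstruction of the odor network and its
    published chemotaxis table ship as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
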