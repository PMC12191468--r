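Package: ioqw
Title: Quantum-Walk-Inspired Identification of Influential Nodes in Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks the nodes of an undirected, unweighted network by spreading
    influence using a discrete-time quantum-walk-inspired score (IOQW). The
    walker carries a two-state "stay/move" coin; the coin operator blends
    adjacency with all-pairs shortest-path lengths, the shift operator is the
    direct sum of the identity and the degree-normalised adjacency, and a
    degree-weighted projective measurement after two walk steps yields
    per-node influence scores. Includes classical centrality baselines
    (degree, betweenness, PageRank), a reference one-dimensional coined
    quantum walk, a discrete-time SIR spreading simulator for ground-truth
    influence, Kendall tau (tau-a) ranking agreement, edge-list input/output,
    fixture graphs, random-graph generators, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
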