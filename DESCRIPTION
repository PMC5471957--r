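Package: atria
Title: Iterative Payoff Centrality for Signed Weighted Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks the nodes of a signed, weighted, undirected network by an
    economic payoff: each node's centrality is the magnitude of the summed
    maximum-gain and maximum-loss path products to every other node. The most
    central node is extracted iteratively; before each extraction the third
    edge of every structurally balanced (stable) triad through the selected
    node is ablated, so that leaders, villains and bridge nodes are recovered
    across the whole network instead of clustering in one region. Includes
    weighted degree, closeness and betweenness baselines on the -log|w|
    distance transform, generators for the synthetic network families used to
    benchmark the method (planted-leader and planted-villain cliques, rival
    groups, two triads, two cliques, a five-club planted network, scale-free
    networks), edge-list and GraphML input/output, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
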