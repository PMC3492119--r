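Package: ancnet
Title: Parsimonious Reconstruction of Ancestral Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs histories of interaction gain and loss on gene
    duplication forests by maximum parsimony, and infers common-ancestor
    interaction networks of two extant networks. A network history places
    "flip" events (interaction gains or losses) on the nodes of a
    duplication forest; the parity of flips along root paths determines
    which extant gene pairs interact. The package provides the dynamic
    program that finds minimum-cost flip sets (undirected, directed,
    self-loop, and branch-length-penalized variants), detection and greedy
    removal of blocking loops (cyclic event sets admitting no consistent
    timing), ancestral-network inference from paired duplication forests,
    degree-dependent / degree-independent / duplication-centric network
    growth simulators with ground-truth event logs, and precision/recall
    evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
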