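Package: netcons
Title: Weighted Consensus Trees and Explicit Weighted Consensus Phylogenetic Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers weighted consensus trees and explicit weighted consensus
    phylogenetic networks from collections of gene trees carrying branch
    supports (bootstrap percentages or posterior probabilities) and optional
    per-tree weights. Cluster (bipartition) weights are computed from branch
    and tree supports, a backbone consensus tree is assembled (bootstrap-based
    majority rule, extended majority rule, Nelson, or weight-based extended
    majority rule), and directed weighted reticulation branches representing
    hybridization, intragenic recombination or horizontal gene transfer are
    added using a subtree-prune-and-regraft notion of first-degree
    incompatibility and a Robinson-Foulds direction rule. Includes a
    sliding-window scan of multiple sequence alignments for mosaic genes, a
    self-contained neighbor-joining + bootstrap fallback for tree inference,
    a simulation engine (random trees, clock noise, HKY+Gamma sequences,
    recombination-block injection) and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
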