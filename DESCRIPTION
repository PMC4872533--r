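Package: ppicontrol
Title: Structural Controllability Analysis of Phosphorylation-Based
    Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assembles mixed (partially directed) protein-protein
    interaction networks from kinase/phosphatase-substrate, knockout-pair
    and physical-interaction evidence, orients the undirected portion by
    maximizing satisfied source-target path constraints, classifies every
    node as critical, redundant or ordinary for structural controllability
    via minimum driver-node counts from maximum bipartite matching,
    verifies controllability with the Kalman rank condition, measures
    robustness of the critical-node set to random edge inversion, simulates
    hub (paralog-family) knockdowns through characteristic-path-length
    curves, and tests node and edge annotations (post-translational
    modifications, disorder, interface types, complex membership) for
    class-conditional enrichment. Includes a synthetic-network generator
    with planted effects so the full pipeline is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
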