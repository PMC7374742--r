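Package: netpharm
Title: Network Pharmacology of Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for network-pharmacology inference on protein interaction
    networks: STRING-style edge-list import, graph topology statistics
    (degree distribution with log-log power-law fitting, clustering,
    characteristic path length, betweenness, harmonic closeness and the
    cytoHubba-style BottleNeck score), MCODE molecular-complex detection,
    hypergeometric pathway enrichment with Bonferroni correction and
    kappa-score term grouping, a bottleneck/date-hub key-protein
    prioritization cascade, and deterministic mass-action ODE simulation of
    the MAPK signalling cascade with competitive-inhibitor injection.
    Includes seeded synthetic-data generators and transcribed literature
    fixtures so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    deSolve,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
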