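Package: alliancenet
Title: Multi-Level Alliance Detection in Fission-Fusion Animal Societies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying multi-level male alliances from
    group-composition survey data in fission-fusion societies such as the
    Indo-Pacific bottlenose dolphins of Shark Bay. Computes dyadic
    half-weight association indices (HWI), detects alliance communities by
    average-linkage agglomerative clustering with a modularity-maximised
    dendrogram cut and cophenetic validation, derives within- and
    between-alliance weighted-degree (strength) metrics with temporal
    snapshots, tallies coded affiliative behaviours during inter-alliance
    fusion events (including Cohen's kappa for coder reliability), and
    ships a planted three-level society simulator so every pipeline stage
    is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
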