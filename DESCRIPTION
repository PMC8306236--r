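Package: herbnet
Title: Network Pharmacology of Multi-Component Herbal Medicines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible network-pharmacology pipeline for
    multi-component herbal medicines profiled by in-vivo metabolomics.
    Screens herb constituents (prototype compounds and their metabolites)
    on 16-period plasma fold-change series, predicts protein targets by
    resource diffusion on a substructure-drug-target network, intersects
    known and predicted compound-target interactions with a disease gene
    list to build a bipartite compound-disease-target network, scores hub
    genes by median-rank aggregation of four protein-protein-interaction
    centralities (edge-percolated component, eccentricity, closeness,
    radiality), performs hypergeometric pathway over-representation with
    Benjamini-Hochberg control, and selects critical compound-target
    interactions from docking scores and in-vivo concentrations. Includes
    a synthetic-data generator with planted ground truth so every stage
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
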