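Package: herbnet
Title: Network Pharmacology for Multi-Herb Formulas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for network-pharmacology analysis of multi-compound,
    multi-target herbal formulas: ADME-based screening of bioactive
    compounds (continuous Tanimoto drug-likeness, an eight-descriptor
    half-life regression, and inclusive oral-bioavailability /
    drug-likeness / half-life threshold filters with a per-row audit),
    likelihood-thresholded compound-to-target mapping, bipartite
    compound-target / target-disease / target-pathway network
    construction with degree statistics and hub detection,
    hypergeometric over-representation analysis with function-module
    grouping, and a synthetic-data generator with planted hubs and
    planted enriched terms for end-to-end validation. Ships a worked
    ulcerative-colitis four-herb formula dataset with a deterministic
    degree-sequence reconstruction of its compound-target network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
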