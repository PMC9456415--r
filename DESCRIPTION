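Package: herbscreen
Title: Similarity-Based Toxicity and Drug-Interaction Screening for Herbal Compound Mixtures
Version: 0.1.0
Authors@R:
    person("herbscreen", "maintainers", email = "maintainers@herbscreen.dev",
           role = c("aut", "cre"))
Description: An offline workflow for flagging potential toxicities and drug
    interactions of multi-compound plant extracts from chemical-similarity
    evidence. Provides ADME-based active-compound screening of herbal compound
    tables, ligand-based virtual screening with path and circular fingerprint
    Tanimoto similarity, calibration of a similarity-score threshold from
    first-elusive (FEP-SS) and first-contrast (FCP-SS) prediction-similarity
    scores, aggregation of per-endpoint toxicity verdicts into predictions,
    interaction-text classification and bipartite network export, and
    dose-response synergy quantification (four-parameter logistic fits,
    Combination Index, and zero-interaction-potency delta scores with
    most-synergistic-area detection). Includes seeded synthetic-data
    generators so the full pipeline is testable without any database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
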