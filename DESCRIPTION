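Package: msat
Title: Evidence-Conditioned Heterogeneous Graph Attention for Herb-Adverse
    Reaction Signal Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements MSAT, a multi-scale heterogeneous graph attention
    network for predicting associations between Chinese Materia Medica (CMM)
    and adverse drug reactions (ADRs) from spontaneous-report evidence and
    mechanistic biomedical relations. Provides curation of FAERS-like report
    tables into weighted CMM-ADR associations, a typed heterogeneous graph
    container with leakage-safe edge removal, six-dimensional edge-evidence
    featurization, an attention encoder with an evidence-semantic adaptive
    gate and hierarchical signal propagation layers, a hub-calibrated link
    scorer, a cross-validation protocol stack (type-constrained negative
    sampling, imbalance stress tests, cold-start splits, degree-stratified
    reporting), rule-based mapping of MedDRA Preferred Terms to Traditional
    Chinese Medicine functional systems, and a seeded synthetic-data
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
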