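Package: pkaqsar
Title: QSAR Modeling of Aqueous pKa with Curation, Routing and
    Applicability-Domain Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds quantitative structure-activity relationship (QSAR)
    models of aqueous acid dissociation constants (pKa) from
    SMILES-annotated measurement tables. Covers standardization of raw
    records to QSAR-ready parent structures (salt, solvent and counterion
    stripping, mixture and inorganic rejection, tautomer normalization),
    replicate-aware construction of acidic, basic and combined modeling
    sets under three replicate-handling options with
    distribution-preserving train/test splits, 1D/2D descriptor,
    fingerprint and fragment-count featurization through OpenBabel,
    genetic-algorithm descriptor selection scored by cross-validated
    balanced accuracy, a k-nearest-neighbour acid/base/amphoteric router
    with an ionizability checker, support-vector, gradient-boosted and
    neural-network pKa regressors, global (leverage) and local
    (Tanimoto nearest-neighbour) applicability-domain indices with
    per-prediction accuracy estimates, and pairwise +/- 2 pKa-unit
    concordance benchmarking with bootstrap confidence intervals. A
    deterministic synthetic record generator with a group-contribution
    pKa oracle supports end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineOB,
    e1071,
    xgboost,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
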