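Package: gpcrscreen
Title: Consensus Virtual Screening Against G Protein-Coupled Receptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A ligand-based and structure-based decision-support pipeline for
    virtual screening against G protein-coupled receptor (GPCR) panels.
    Small molecules and peptide ligands share one feature space: peptides are
    truncated to their six-residue activation fragment, converted to SMILES,
    and fingerprinted with ECFP4 (Morgan radius 2) bit vectors alongside small
    molecules.  Per receptor and binding-site mode the package trains a
    feed-forward multiclass activity classifier (six pChEMBL ranges) and a
    gradient-boosted pChEMBL regressor under randomized hyperparameter search
    with 10-fold cross-validation, decodes the most important fingerprint bits
    back to chemical fragments by split gain, wraps a docking leg with
    ligand-centered 30 Angstrom cubic search boxes, and combines the three
    legs into a k-of-3 consensus target call evaluated by precision.
    A planted structure-activity generator provides fully synthetic
    benchmarks so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    xgboost,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
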