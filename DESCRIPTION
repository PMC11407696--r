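Package: ddgmem
Title: Sequence-Based Prediction of Binding Free Energy Changes in
    Membrane Protein-Protein Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for predicting the change in binding free energy
    (ddG, kcal/mol) caused by single amino-acid mutations in membrane
    protein-protein complexes, from sequence alone. Implements curation
    of mutation binding-affinity tables (discrepancy correction,
    replicate filtering, sign-conflict resolution, duplicate merging,
    structure-to-sequence renumbering), extraction of physicochemical
    (AAIndex), evolutionary (PSSM, Row-PSSM, pseudo-PSSM) and database
    features, a cross-validated gradient-boosted regression protocol
    with random hyperparameter search and averaged feature importance,
    and synthetic fixture generators (random sequences, PSI-BLAST-style
    PSSMs, planted-signal datasets, deliberately defective affinity
    tables) that exercise every stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'aaindex.R'
    'constants.R'
    'curation.R'
    'ddgmem-package.R'
    'features.R'
    'io.R'
    'model.R'
    'mutation.R'
    'pssm.R'
    'simulate.R'
    'utils.R'
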