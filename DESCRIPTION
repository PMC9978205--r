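Package: pepsigna
Title: Graph-Based Structural Signatures for Peptide-Protein Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts peptide-protein complex entries from PDB-format
    structures, computes cutoff-scanning (aCSM-ALL) graph-based structural
    signatures over eight pharmacophore atom categories, derives per-entry
    physicochemical metadata (molecular weight, aromaticity, instability
    index, isoelectric point, hydrophobic fraction, buried surface area),
    and evaluates signature datasets with a stratified multi-model
    classification protocol. Includes deterministic synthetic-structure
    generators so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    nnet,
    pROC,
    randomForest,
    rpart,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    bio3d
Config/testthat/edition: 3
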