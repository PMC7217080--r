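Package: sevc
Title: Soft Ensemble Vote Classification of Protein Construct Solubility
    from Hydrophobicity Scales
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Binary solubility classification of engineered protein
    constructs (e.g. chimeric virus-like particle scaffolds carrying
    peptide inserts) from amino-acid sequence alone.  Each published
    hydrophobicity scale defines one feature (the summed per-residue
    hydrophobicity over the variable sequence window) and one one-level
    decision tree (decision stump) induced with Gini's diversity index.
    Stumps are ranked by an embedded feature-selection step (training-set
    accuracy) and combined by soft ensemble voting: each stump contributes
    its child-node class probability to its decided class, and the class
    with the larger probability sum wins.  The package also provides
    stratified construct sampling with per-stratum caps, Monte Carlo
    cross-validation, a training-size by ensemble-size learning
    experiment, stratum-level misclassification analysis, charge and
    lysine/arginine-ratio baselines, and a synthetic construct-grid
    generator for testing the whole pipeline without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    seqinr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
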