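Package: snapqsar
Title: Image-Based QSAR Modeling from Multi-Angle 3D Molecular Snapshots
Version: 0.1.0
Authors@R: person("snapqsar", "developers", role = c("aut", "cre"),
    email = "snapqsar@example.org")
Description: A sequential pipeline for image-based quantitative
    structure-activity relationship (QSAR) modeling of agonist/antagonist
    bioassay activity. Activity tables (SMILES plus raw well readings or
    0-100 activity scores) are normalized, labeled and split; each compound
    is embedded as a single explicit-hydrogen 3D conformer (RDKit via the
    system Python) and written to SDF V2000; deterministic 256x256 RGB
    ball-and-stick snapshots are rasterized at user-defined angle increments
    on the x, y and z axes with configurable background colors; a small
    convolutional network is trained on the snapshots with early stopping on
    validation loss; and models are scored with a full binary-classification
    metric suite (sensitivity, specificity, balanced accuracy, MCC, F,
    Youden cutoff, ROC AUC, PR AUC). Includes a seedable toy-assay generator
    with a structure-correlated activity signal so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on
    the PATH, for SMILES ingestion and 3D embedding.
Config/testthat/edition: 3
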