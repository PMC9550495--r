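Package: conswat
Title: Conserved Water Molecule Prediction in Protein Binding Sites
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies conserved water molecules (CWMs) in the binding
    sites of protein-ligand crystal structures. Provides homolog
    superposition based labeling of binding-site waters (rigid-body
    least-squares fit, RMSD filtering, ligand-distance pocket definition
    and nearest-water Euclidean distances), six formula-defined
    microenvironment features per water (atom density, mobility,
    temperature B-factor, atomic hydrophilicity, atomic hydrophobicity
    and solvent-accessible surface area), exhaustive feature-combination
    evaluation across seven classifier families with stratified five-fold
    cross-validation, tolerance-aware ranking of combinations, and
    training/prediction with the selected ensemble model. A synthetic
    module generates toy homolog structure pairs with planted ground
    truth and labeled feature tables for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    MASS,
    class,
    e1071,
    rpart,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
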