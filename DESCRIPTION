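Package: allopocket
Title: Allosteric Site Prediction from FPocket Descriptors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for predicting allosteric binding sites on
    proteins from FPocket pocket descriptors. Parses PDB structures and
    FPocket output directories, assigns binary allosteric labels to pockets
    by modulator contact or closest-centroid rules, mitigates the strong
    class imbalance of pocket data by rank-cutoff under-sampling, trains a
    bagged and greedily weighted ensemble of tabular classifiers, and
    evaluates both classifying power (accuracy, precision, recall, F1) and
    ranking power (top-k probabilities). Includes a synthetic-fixture
    generator that emulates the statistical structure of curated
    allosteric-protein benchmarks, and command-line entry points with a
    JSON prediction interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    class,
    glmnet,
    jsonlite,
    nnet,
    ranger,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
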