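Package: rasarstack
Title: Read-Across Augmented QSAR, ARKA and Stacked PLS Models for Aquatic Toxicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building similarity-augmented quantitative
    structure-activity relationship (q-RASAR) models of acute aquatic
    toxicity (pLC50), as applied to multispecies salmon LC50 data.
    Covers structure input and curation from SMILES/SDF/CSV, the six
    2D descriptors used by the published salmon models (H-053, NsssCH,
    B02[N-N], B02[S-S], B03[N-O], Wildman-Crippen LOGP99), descriptor
    pretreatment, four train/test division schemes, best-subset and
    genetic-algorithm feature selection, kernel-based read-across
    prediction with hyperparameter optimization, the 18-column RASAR
    descriptor block, ARKA supervised dimensionality reduction with
    activity-cliff diagnostics, NIPALS partial least squares, linear
    discriminant and bagged-tree classifiers, stacked meta-models, a
    full validation suite (R2, Q2_LOO, Q2_F1/F2, CCC, MAE, RMSEp,
    Y-randomization, DModX applicability domain), and a frozen
    predictor exposing the published salmon pLC50 equations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    MASS,
    cluster,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
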