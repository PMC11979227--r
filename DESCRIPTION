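Package: leafcure
Title: Image-Based Moisture Prediction for Air-Cured Leaves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Non-destructive estimation of leaf moisture content during
    air-curing from paired front/rear photographs of naturally suspended
    leaves. Provides dual-mask (HSV colour threshold + Otsu) leaf
    segmentation, colour statistics in RGB and CIELAB, grey-level
    co-occurrence matrix (GLCM) Haralick texture features, a two-step
    Pearson-correlation feature filter, a genetic-algorithm tuned
    two-layer stacking ensemble regressor selected by entropy-weighted
    cross-validation scoring, and permutation-sampling Shapley-value
    attribution of the fitted model. A synthetic-data module generates
    leaf images and feature tables emulating the composition of a full
    air-curing campaign so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    igraph,
    e1071,
    nnet,
    ranger,
    rpart,
    xgboost,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    jpeg,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
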