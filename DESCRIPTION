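Package: oliveshape
Title: Geometric Morphometrics and Stacked Classification of Olive Organ Silhouettes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated discrimination of olive (Olea europaea) cultivars from
    binary silhouettes of fruits, leaves and endocarps. Segments single-organ
    images into calibrated silhouettes, extracts orientation-normalized
    contours, computes organ-specific shape descriptor catalogs (24 fruit, 16
    leaf, 22 endocarp), trains per-organ probabilistic classifiers and a
    stacking meta-classifier over their out-of-fold probability matrices, and
    attributes classification decisions to descriptors and organs with Shapley
    values. Includes a synthetic silhouette generator with analytic ground
    truth so the whole pipeline is testable without field data, plus
    exploratory tools (PCA, coefficient-of-variation tables, Ward dendrograms,
    violin-plot summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    png,
    signal,
    igraph,
    ape,
    xgboost,
    randomForest,
    caret,
    e1071,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
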