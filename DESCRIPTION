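Package: metaboshap
Title: Exact Shapley Explanations and PLS-DA VIP Scores for Metabolomics Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interpretable binary classification for metabolomics feature
    tables. Implements exact Shapley-value attribution for tree-ensemble
    classifiers twice over -- a brute-force coalition enumeration and a
    polynomial-time tree algorithm that provably agree -- together with a
    NIPALS PLS1 discriminant model and Wold's VIP scores, volcano-style
    feature selection with log/autoscale preprocessing, a minimal reference
    random-forest trainer with per-node training cover, the downstream
    explanation analytics (global importance, beeswarm, PCA embedding of
    explanations, supervised clustering, dependence data, waterfall/force
    decompositions, confusion-rate error analysis), an end-to-end pipeline,
    and a synthetic log-normal data generator with planted effects so every
    component is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    yaml,
    optparse,
    randomForest,
    pROC,
    cluster,
    withr
Config/testthat/edition: 3
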