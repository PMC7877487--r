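Package: morphnet
Title: Individual Morphological Covariance Brain Networks and CNN Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs individual-level morphological covariance brain networks
    from parcellated gray-matter volume maps (per-region kernel density
    estimation, symmetric Kullback-Leibler divergence, KLS similarity edges),
    classifies the resulting similarity matrices with a five-stage bottleneck
    residual convolutional network trained by Adam on binary cross-entropy,
    localizes the connectivities driving classification with Grad-CAM, and
    evaluates the pipeline with nested cross-validation, conventional
    machine-learning baselines, and a label-flip permutation test. A synthetic
    cohort generator emulates multisite preprocessed structural MRI inputs so
    the full pipeline runs without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml,
    pROC,
    glmnet,
    ranger,
    e1071,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
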