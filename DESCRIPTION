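Package: kneeSSM
Title: Statistical Shape Modelling of the Tibiofemoral Joint
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds statistical shape models (SSMs) of the distal femur,
    proximal tibia and combined tibiofemoral joint from corresponded
    triangular surface meshes, and relates the resulting shape-mode
    weights to clinical outcome after partial medial meniscectomy.
    Provides mesh input/output (PLY, STL, OBJ), dense template
    correspondence by rigid then elastic registration, rigid generalized
    Procrustes alignment without scaling, PCA mode decomposition with
    compactness and leave-one-out generalization metrics, group
    statistics on demographics and principal-component weights,
    leave-one-out logistic prediction of treatment response with
    bootstrap confidence intervals, and a synthetic bone-shaped cohort
    generator with planted modes of shape variation for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
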