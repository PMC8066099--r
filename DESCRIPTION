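Package: radiopcr
Title: MRI Radiomics Pipeline for Predicting Pathological Complete Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end radiomics workflow for predicting pathological
    complete response (pCR) after neoadjuvant chemoradiotherapy from
    pretreatment T2-weighted MRI of locally advanced cervical cancer.
    Provides planar resampling, a Laplacian-of-Gaussian filter bank,
    intensity-based ROI normalisation with threshold-pair subpopulation
    masks, first-order/GLCM/fractal/morphological feature extraction,
    stability-based univariate feature selection with significance voting
    and Pearson correlation pruning, repeated cross-validated AUC model
    selection over a fifteen-classifier roster, and Youden-index operating
    point evaluation. Includes a seeded synthetic lesion-phantom generator
    so the full pipeline can be exercised and calibrated without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    RNifti,
    igraph,
    randomForest,
    e1071,
    nnet,
    rpart,
    glmnet,
    mclust,
    xgboost,
    caret,
    mixOmics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
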