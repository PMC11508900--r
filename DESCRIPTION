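Package: ensdm
Title: Ensemble Species Distribution Modelling on Gridded Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for ensemble species distribution
    modelling (SDM): environmental-variable screening by pairwise Pearson
    correlation and permutation importance, a nine-learner committee
    (ANN, CTA, FDA, GBM, GLM, MARS, a MaxEnt-style penalised regression,
    RF, and a surface range envelope) combined by metric-weighted
    averaging, threshold-free (AUC) and threshold-based (Kappa, TSS)
    evaluation on repeated stratified splits, natural-breaks habitat
    classification with geodesic area accounting, land-use
    cross-tabulation and correlation, and distribution-centroid shift
    tracking across climate periods. Includes a synthetic-landscape
    generator (Gaussian random field covariates, known suitability
    surface, coupled land-use layer) so the full pipeline is testable
    end-to-end and parameter recovery is measurable without external
    raster downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    glmnet,
    jsonlite,
    MASS,
    nnet,
    purrr,
    randomForest,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
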