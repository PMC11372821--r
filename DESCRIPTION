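Package: nichecast
Title: Ensemble Habitat Suitability Models, Niche Hypervolumes and Marine
    Protected Area Gap Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for marine species distribution
    modelling at species and population level: occurrence cleaning,
    grid-cell thinning and balanced pseudo-absence generation;
    collinearity screening (pairwise Pearson correlation and variance
    inflation factors) and principal component analysis of environmental
    predictors; kernel-density niche hypervolumes with Monte-Carlo volume
    estimation and decomposition of pairwise niche difference into shift
    and contraction/expansion components; a gated, weighted ensemble of
    ten suitability learners evaluated by replicated stratified
    cross-validation with the true skill statistic and AUC; projection
    onto current and future climate scenario rasters with maxTSS
    binarisation, change maps and range-change percentages; and overlay
    of suitable habitat with marine protected areas to quantify
    protection gaps and priority conservation areas. Includes a synthetic
    data generator (autocorrelated predictor fields, Gaussian niche
    occurrence sampling, scenario deltas, rectangular protected areas) so
    the whole analysis runs without external downloads. Rasters are read
    and written as plain-text ESRI ASCII grids; vector inputs as GeoJSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    mgcv,
    nnet,
    rpart,
    randomForest,
    xgboost,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
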