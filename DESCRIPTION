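Package: admarkers
Title: Clustering and Random-Forest Feature Selection for Alzheimer's
    Disease Biomarker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analyses a panel of 27 Alzheimer's disease biomarkers drawn
    from PET, MRI, cerebrospinal fluid and plasma under realistic
    missingness. Builds pairwise-complete absolute Spearman similarity
    matrices, performs WPGMA agglomerative hierarchical clustering with a
    permutation-averaged PCA elbow rule for the cluster count, and ranks
    predictors of amyloid-PET positivity and cognitive impairment with a
    from-scratch random forest that uses curvature-test split-variable
    selection, surrogate splits for missing values, pruning and
    Gaussian-process Bayesian hyperparameter optimization inside a gated
    cross-validation protocol. Includes a seeded synthetic-cohort
    generator with planted correlation blocks and group effects so the
    entire pipeline is testable without access to the original cohort.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    randomForest,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
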