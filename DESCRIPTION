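Package: voxelmeta
Title: Mass-Univariate Mega- and Meta-Analysis of Multi-Site Voxelwise
    Imaging Data with Per-Feature Missingness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A unified engine for mass-univariate analysis of multi-site
    voxelwise neuroimaging data. Fits a regression model at every voxel using
    only the subjects with observed data there, so the sample size and degrees
    of freedom vary across the brain instead of discarding incompletely
    covered voxels. Supports fixed-effect linear and generalized linear
    models and linear mixed models with a site random intercept
    (mega-analysis), site-wise fitting with Stouffer or Fisher combination of
    site-level results (meta-analysis), Benjamini-Hochberg false discovery
    rate correction, probabilistic threshold-free cluster enhancement with
    Gaussian-random-field family-wise error control, suprathreshold cluster
    tables, and five conjunction rules for comparing aligned statistic maps.
    Includes a simulation benchmark that embeds a spherical effect in
    standard-normal noise volumes, injects per-voxel missingness completely
    at random, and scores detection by ROC AUC and sensitivity at a fixed
    false positive rate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    Rcpp,
    RNifti,
    lme4,
    yaml,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    readxl,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
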