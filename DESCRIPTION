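Package: mediablend
Title: Systematic Media-Blending Design and Analysis for Cell-Culture Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis toolkit for screening cell-culture medium
    components by media blending. Enumerates blend combinations of mother
    media, projects rank-deficient composition matrices into an orthogonal
    principal-component space, and selects experimental conditions by
    D-optimal random search with multicollinearity diagnostics (pairwise
    correlations and variance inflation factors). Fits a suite of linear and
    nonlinear regression models under a grouped train/test and
    cross-validation protocol, selects superior models against a
    predict-the-mean baseline with Holm-corrected one-sided paired t-tests,
    and ranks medium components by permutation feature importance, including
    a correlation-adjusted variant that co-shuffles correlated components
    using shrunk Fisher-z correlation estimates. Also simulates dedicated
    mother-media sets with low intercomponent correlation and provides a
    synthetic-data generator that emulates the statistical structure of
    commercial chemically defined media.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Rcpp,
    glmnet,
    e1071,
    kernlab,
    ranger,
    xgboost,
    mixOmics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
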