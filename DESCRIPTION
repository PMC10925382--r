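Package: knocksum
Title: FDR-Controlled Variable Selection from Summary Statistics with
    Knockoffs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Controlled variable selection with false discovery rate (FDR)
    guarantees when only study summary statistics are available: per-variable
    score vectors X'Y, the response norm ||Y||^2, the sample size, and a
    covariance (linkage-disequilibrium) matrix, optionally the empirical Gram
    matrix X'X. Implements Gaussian model-X knockoff construction from a
    covariance matrix, direct sampling of knockoff Z-scores from summary
    statistics, penalized-regression importance statistics (fixed-penalty
    lasso, square-root lasso, lasso-max entry values, and a pseudo-lasso on
    population covariance blocks with lasso-min and pseudo-summary-statistic
    penalty tuning), single- and multi-knockoff selection filters, and a
    simulation harness that measures empirical FDR and power on Gaussian,
    autoregressive, and genotype-like designs.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
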