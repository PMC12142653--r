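Package: pfcrsvr
Title: Robust Hybrid Support Vector Regression with Principal and Principal
    Fitted Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits linear support vector regression with a bounded exponential
    quantile loss (EQSVR), solved by the concave-convex procedure with a
    clipped dual coordinate descent inner solver, and its hybrid variants that
    regress on principal components or principal fitted components (PCRSVR,
    PFCRSVR) to handle multicollinearity, vertical outliers and larger
    predictor sets simultaneously. Includes the classical epsilon-SVR baseline
    and its component-space hybrids for comparison, a Monte Carlo engine for
    collinear, outlier-contaminated benchmark data with MSE/MAE/PMSE summaries
    of coefficient estimation error, and a bootstrap evaluator reporting the
    mean standard error of bootstrap coefficient estimates on real tabular
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
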