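Package: tempclass
Title: Temporal Classification of Short Omics Time Series with
    Shape-Constrained Smoothing Splines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models short replicate time-series signals (proteins,
    transcripts, metabolites) with variance-weighted natural cubic
    smoothing splines under interval-wise monotonicity constraints,
    solved as a quadratic program by a primal active-set method.  The
    smoothing parameter is chosen per shape by a modified generalized
    cross-validation score and the final shape by an extrema-penalized
    small-sample AIC, yielding a temporal class label for every signal
    (e.g. "Min3,Max4", "I", "D", "C").  Includes a k-means/gap-statistic
    clustering baseline, leave-one-time-point-out robustness analysis
    against interpolating fitters, and a synthetic-data generator with
    known ground-truth shape classes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
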