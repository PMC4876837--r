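Package: sammeta
Title: Split, Analyze, and Meta-Analyze Large Tabular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyze datasets too large for a single model fit by splitting them
    into pseudo-studies, fitting a statistical model to each study to obtain
    effect sizes with sampling covariance matrices, and pooling the effect
    sizes with multivariate fixed-, random-, or mixed-effects meta-analysis or
    two-stage structural equation modeling. Includes bounded-memory readers for
    CSV and SQLite sources, per-study estimators (multiple regression,
    mediation via the delta method, coefficient alpha, correlation matrices
    with normal-theory asymptotic covariances, crossed random-intercept mixed
    models), REML estimation of between-study variance components,
    heterogeneity (I-squared) and moderator (R-squared) statistics, confidence
    ellipses for bivariate effects, pooled-correlation factor analysis by
    weighted least squares, synthetic-data generators with machine-readable
    truth records, and a configuration-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    DBI,
    RSQLite,
    jsonlite,
    yaml,
    lme4,
    MASS,
    withr
Suggests:
    testthat (>= 3.0.0),
    metafor,
    Matrix,
    optparse
Config/testthat/edition: 3
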