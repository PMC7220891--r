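Package: dbmgeo
Title: Model-Based Geostatistical Mapping of Childhood Overweight and Wasting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Small-area estimation of childhood wasting and overweight prevalence
    from cluster-level survey counts, using a two-stage continuation-ratio
    binomial model with a Matern x AR1 space-time Gaussian process, country and
    nugget random effects, and stacked-ensemble covariates fitted by Laplace
    approximation. Includes anthropometric z-score computation from LMS growth
    references, seasonality adjustment of weight-for-height z-scores,
    population-weighted resampling of polygon-referenced observations,
    draw-based post-estimation (masking, administrative aggregation,
    recency-weighted annualized-rate-of-change projection, double-burden
    classification), spatially stratified cross-validation, and a fully
    synthetic world generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    glmnet,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
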