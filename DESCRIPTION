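Package: lawbend
Title: Piecewise Change-Point Trend Models for Injury Surveillance Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interrupted time-series analysis of sports-injury surveillance
    counts aligned to staggered policy dates. Fits piecewise log-linear
    negative-binomial mixed models with an athlete-exposure offset, a state
    random intercept integrated by adaptive Gauss-Hermite quadrature, and two
    unknown change points estimated by an exhaustive profile-likelihood scan
    over a six-month grid. Includes a synthetic surveillance-data generator
    with known piecewise rate structure for parameter-recovery studies,
    ingest and exclusion filters for event and exposure records, law-language
    stratification, slope inference on the percent-per-month scale, group
    comparisons, cluster bootstrap diagnostics, and report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    glmmTMB,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
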