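Package: selresp
Title: Selection Response Probabilities from Genomic Prediction in
    Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses the expected response to truncation selection in
    genomic-prediction based breeding programs evaluated in
    multi-environment trials.  Fits GBLUP linear mixed models (two-stage
    with Smith weights or single-stage) by average-information REML with a
    VanRaden genomic relationship matrix, partitions the apparent genomic
    variance of a single-year trial into breeding-value and
    value-by-year components through a long-term variance ratio, and
    simulates from the joint multivariate-normal distribution of true
    breeding values and their BLUPs to estimate the probability that the
    top n entries ranked on GBLUPs contain the m truly best entries.
    Includes a synthetic data generator for sparse testcross trial
    networks (alpha-design trials, multiple testers, locations and years)
    so the whole pipeline can be exercised without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    MASS,
    lme4,
    withr,
    optparse
Config/testthat/edition: 3
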