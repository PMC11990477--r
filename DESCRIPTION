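Package: vinosense
Title: Odor Activity Value Profiling and Electronic-Nose Chemometrics for Wine Aroma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for aroma profiling of wines from quantified volatile
    compounds and quartz-microbalance electronic-nose sensor arrays.
    Computes odor activity values (OAV) from concentrations and odor
    perception thresholds, flags aroma-active compounds, and aggregates
    OAVs into eleven odorant-series scores. Implements the accompanying
    chemometric stack: column auto-scaling, principal component analysis,
    NIPALS partial least squares discriminant analysis with variable
    importance in projection (VIP) scores, venetian-blind cross-validation,
    confusion matrices, principal component regression with calibration and
    cross-validation error metrics (RMSEC, RMSECV, R2, RPD), and Pearson
    correlation maps between sensor responses and odorant series. A
    synthetic-data generator emulates class-structured wine datasets with a
    linear sensor-response model so every pipeline stage can be exercised
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown,
    withr
Config/testthat/edition: 3
VignetteBuilder: knitr
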