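Package: retinaicp
Title: Retinal Arteriole/Venule Ratio Analysis for Non-Invasive
    Intracranial Pressure Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating intracranial pressure (ICP) non-invasively
    from monochrome fundus video. Implements a classical image-analysis
    pipeline that triages video frames, localises the optic disc, scores
    focus with the Tenengrad gradient metric, segments retinal vessels with
    a Frangi vesselness filter, measures sub-pixel vessel widths along
    skeleton-perpendicular intensity profiles, and computes the
    arteriole/venule (A/V) area ratio. Time-matches A/V observations to ICP
    recordings by windowed averaging, and analyses the resulting
    hierarchical data with stratified random-intercept mixed models, Wald
    slope comparisons, intraclass correlation, and diagnostic (ROC)
    summaries. Ships phantom fundus-frame and synthetic NICU cohort
    generators so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    png,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
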