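Package: vocmix
Title: Cumulative Risk Assessment for Occupational VOC and Aldehyde Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening-level cumulative risk assessment of personal
    exposure measurements of volatile organic compounds (VOCs) and aldehydes,
    as collected in occupational hygiene campaigns such as hair-salon surveys.
    Measurements are held in a SummarizedExperiment-derived container with
    explicit reporting-limit censoring; chemicals are resolved to health-based
    reference values through a tiered reference-value / occupational exposure
    limit hierarchy; and per-worker and per-salon hazard quotients, hazard
    indices, total VOC (TVOC) concentrations and maximum cumulative ratios
    (MCR) are computed and classified into MCR substance groups. Descriptive
    statistics for left-censored lognormal exposure data, between/within-salon
    variance components, one-way ANOVA with Bonferroni pairwise comparisons,
    ordinary least squares fits, and a synthetic campaign generator for
    validation studies are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
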