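Package: mlclust
Title: Multilayer Clustering of Longitudinal At-Risk Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies longitudinal cohorts of subjects at risk of dementia
    (mild cognitive impairment) into prognostically homogeneous clusters.
    Builds rule-coverage example similarity tables (EST) per data layer by
    discriminating original from randomized instances with an ensemble of
    bagged decision rules, then agglomerates subjects by minimizing
    clustering-related variability (CRV) jointly across a baseline layer and
    a longitudinal-slope layer (merges require a positive variability
    reduction in every layer). Includes a synthetic-cohort generator with
    planted decliner clusters, cluster profiling (Mann-Whitney, chi-square,
    conversion/reversion rates), Spearman correlation networks, and
    subgroup-discovery cut-off classifiers for flagging rapid decliners with
    cross-cohort validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rpart,
    igraph,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
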