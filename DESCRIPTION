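Package: coexSplit
Title: Rank-Based Coexpression, Greedy Cohort Splitting and Survival
    Comparison for Gene Pairs
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to ask whether the coexpression of a gene pair carries
    prognostic information in a patient cohort. Expression values are
    converted, sample by sample, to percentile ranks on a 0-100 scale;
    coexpression of two genes is measured by the Pearson correlation of
    their rank profiles; a greedy leave-one-out procedure partitions the
    cohort into a correlation-maximised subgroup ("interaction" cohort)
    and the removed remainder; and the two cohorts are compared by
    Kaplan-Meier estimation and the two-group log-rank test. Single-gene
    high/low marker survival analysis and a synthetic-data generator
    (planted correlated subpopulation, proportional-hazards survival with
    independent right-censoring) are included so that the whole pipeline
    runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GeneExpression, Survival, Transcriptomics, Microarray
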