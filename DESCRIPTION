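Package: stressrank
Title: Time-Course Ranking, Enrichment and Information Clustering for
    Acute-Stress Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for short time-course expression studies with
    one control group and several treatment time points, modelled on acute
    restraint-stress profiling of mouse hippocampus. Computes per-gene log2
    ratio trajectories from replicate medians, ranks genes by the sum of
    squared log2 ratios across the time course, selects and truncates a
    top-K heatmap matrix, tests gene sets for over-representation
    (hypergeometric) or rank-based enrichment with Bonferroni control, and
    clusters significant term gene sets by variation of information.
    Includes a synthetic cohort and gene-set generator with planted ground
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
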