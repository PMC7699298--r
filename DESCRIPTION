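Package: mirtrend
Title: Trend-Based Screening of miRNA Regulatory Effects in Cancer Stem
    Cell Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for quantifying the regulatory footprint of
    a microRNA across matched cell-culture contexts. The core is a
    genome-wide screen that classifies genes as promoted or inhibited by a
    miRNA from ordered inhibitor/control/mimic treatments in monolayer and
    cancer-stem-cell (CSC) cultures, using Jonckheere-Terpstra trend
    statistics with permutation empirical p-values and an exact
    small-sample mode, followed by weighted Kolmogorov-Smirnov pathway
    enrichment. Supporting stages cover TMM-normalised pooled small-RNA-seq
    group comparisons, relative qPCR quantification by the 2^-ddCt method
    with single- or multi-reference normalisation, and DerSimonian-Laird
    random-effects meta-analysis of standardized mean differences. Seeded
    synthetic-data generators with known ground truth make every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    edgeR,
    jsonlite,
    stats,
    utils
Suggests:
    fgsea,
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
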