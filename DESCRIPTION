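Package: spheroprot
Title: Multi-Batch Isobaric-Labeling Differential Proteomics for 3D
    Spheroid versus 2D Monolayer Comparisons
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for multiplexed (TMTpro)
    reporter-ion proteomics spanning several mass-spectrometry batches:
    pooled-reference channel normalization, zero handling, sample-wise
    median normalization, row-wise one-way ANOVA differential calling
    with fold-change thresholds, cross-cell-line concordance
    classification, plasma-membrane annotation ratio analysis,
    hypergeometric over-representation and weighted running-sum gene-set
    enrichment statistics, and four-parameter logistic GI50 dose-response
    fitting. Includes a ground-truth-labeled synthetic data generator
    emulating a 4 cell-line x {2D,3D} x 3 replicate design spread over 4
    TMTpro batches with pooled reference channels, multiplicative batch
    effects, sparse zeros and spiked contaminants, so that every stage is
    testable without access to raw repository data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
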