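Package: refscreen
Title: Reference-Gene Evaluation for qPCR Time-Course Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating candidate reference (housekeeping) genes in
    quantitative PCR time-course experiments. Implements pre-analytic Ct
    processing (missing-value classification, imputation, gene filtering and
    the Laplace-corrected 41-Ct transform), delta-Ct normalization against
    single or multiple reference genes, per-gene differential-regulation
    testing (one-way ANOVA and Kruskal-Wallis with Benjamini-Hochberg
    correction), stability screening by median absolute deviation and by the
    geNorm M statistic with stepwise exclusion ranking, and quantification of
    the artifacts introduced by normalizing against an unstable reference
    gene. A synthetic Ct-matrix simulator with known ground truth makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
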