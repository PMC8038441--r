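Package: emtquad
Title: EMT Quadrant Classification and Isoform-Level Prognostic Analysis for
    NSCLC Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for isoform-level prognostic analysis of
    non-small-cell lung cancer expression cohorts: a 14-marker rank-quadrant
    classifier of hybrid epithelial/mesenchymal (EMT) states, expression-cutoff
    survival stratification with Kaplan-Meier curves, log-rank tests and
    univariate hazard ratios (overall and within each EMT phenotype), ternary
    drug-response categorization from IC50/EC50 values with resistant-versus-
    sensitive differential expression, two-point control-anchored normalization
    and threshold calling of CRISPR/RNAi gene-effect scores, and comparative-
    threshold (2^-ddCt) qPCR quantification.  A synthetic-data module generates
    tumor cohorts, cell-line panels and qPCR plates with the statistical
    structure these analyses assume, so the whole pipeline is testable without
    external accessions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
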