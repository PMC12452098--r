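Package: icisig
Title: CD8+ T-Cell Multi-Omics Signatures of Immune Checkpoint Inhibitor Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for discriminating long-term responders from
    non-responders to immune checkpoint inhibition from blood CD8+ T-cell
    CITE-seq and paired TCR data: simulation of multi-donor cohorts with
    planted group effects, per-cell quality control and normalization
    (log-normalized RNA, isotype-anchored denoised ADT), marker-panel subset
    annotation and composition tests, pseudobulk Wilcoxon differential
    expression with hypergeometric over-representation, TCR clonotype
    diversity and dynamics statistics, a leave-one-sample-out elastic-net
    response classifier with signature extraction, and module-score
    signature transfer to independent cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
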