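Package: switchscan
Title: Regulator-Conditioned Isoform Switch Detection in RNA-Seq Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis toolkit for discovering splicing-regulator-coupled
    isoform switches in bulk RNA-seq cohorts. Implements correlation-difference
    switch scoring of two-isoform genes against a regulator expression
    gradient, a rank-based top-scoring-pair (kTSP-style) two-group score,
    percent-spliced-in (PSI) estimation from exon-junction counts, pairwise
    classification of alternative-splicing events into the seven canonical
    types (SE, RI, A3, A5, AF, AL, MX), TPM normalization, fold-change-based
    patient stratification with Kaplan-Meier and log-rank survival analysis,
    a threshold differential-expression filter, and in-silico RT-PCR amplicon
    prediction. Ships a synthetic cohort generator that emulates the
    statistical structure of a regulator-graded cancer cell-line panel so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    BiocGenerics
Config/testthat/edition: 3
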