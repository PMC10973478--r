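Package: immunatlas
Title: Multi-Organ Immune Cell Atlas Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing multi-organ single-cell immune
    atlases from raw count matrices: CD45+ (PTPRC) gating and quality control,
    hypergeometric cluster-by-organ composition testing, pseudobulk profiles
    and organ-organ Pearson correlation, one-vs-rest Wilcoxon differential
    expression with the 40-cell and 50-percent-expressing gates, detection of
    organ-specific gene signatures with a cross-cell-type sharing analysis,
    rank-based per-cell module scoring (UCell statistic), single-sample and
    preranked gene set enrichment analysis, and a negative-binomial atlas
    simulator that plants known organ-specific genes, cell-type markers and
    active gene modules so every stage can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
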