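Package: ctvmm
Title: Cell Type-Specific Variance Mixed Models for Single-Cell Pseudobulk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions interindividual gene-expression variation in
    single-cell RNA-seq pseudobulk data into cell type-shared and cell
    type-specific components using variance-component linear mixed models.
    Provides aggregation of cell-level expression into overall (OP) and cell
    type-specific (CTP) pseudobulk with per-entry noise variances, ML, REML
    and Haseman-Elston estimation of the Hom, IID, Free and Full covariance
    structures, likelihood-ratio and Wald tests for cell type-specific
    variance with Fisher-information or delete-one jackknife precision
    matrices, low-rank and multivariate-normal imputation of structured
    missing pseudobulk entries, a simulation engine for calibration and
    power studies, and transcriptome-level variance-decomposition summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
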