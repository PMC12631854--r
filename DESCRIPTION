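Package: snClock
Title: Cell-Type-Specific Transcriptomic Aging Clocks from Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates cell-type-specific transcriptomic aging clocks from
    single-nucleus RNA-seq count data. Provides quality control and log-normalization of
    nucleus-level count matrices, simple and bootstrapped pseudobulk aggregation per donor
    and cell type (including glia/neuron/all-cells levels and the 80%-coverage rule for
    choosing the number of cells sampled), elastic-net age regression with donor-level
    5-fold cross-validation and a naive-mean baseline, feature-gene extraction and overlap
    analysis, transfer of trained clocks to external cohorts with training-mean imputation
    of unmeasured genes and 5-model ensembling, Spearman/Benjamini-Hochberg age-trend
    concordance diagnostics, and residual-based age-acceleration inference with GLM and
    mixed-model disease-versus-control comparisons. A seeded synthetic-cohort generator
    with negative-binomial counts and monotone age-trend genes makes the whole pipeline
    testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    glmnet,
    jsonlite,
    lme4,
    lmerTest,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
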