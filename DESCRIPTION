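Package: immunorewire
Title: Immune Remodeling Analysis for Two-Condition Tumor scRNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify immune remodeling in tumors profiled by
    two-condition (control vs treated) single-cell RNA-seq of sorted CD45+
    cells. Provides a negative-binomial scRNA-seq simulator with planted
    cell-type structure and treatment effects, feature/mitochondrial QC
    filtering and log-normalization, kNN-graph clustering by label
    propagation, marker-sign-panel cluster annotation, ECDF/Kolmogorov-
    Smirnov comparison of marker expression between arms, Wilcoxon
    differential expression with detection-fraction and log-fold-change
    gates, ligand-receptor communication scoring by product of mean
    expression with condition differencing and network community detection,
    and tumor growth-curve permutation testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
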