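Package: scdyneqtl
Title: Dynamic and Cell-State eQTL Mapping from Pooled Single-Cell
    Differentiation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for mapping genetic effects on gene expression along
    a differentiation trajectory from pooled multi-donor single-cell RNA-seq.
    Implements cell quality control and log2(CPM+1) normalisation,
    highly-variable-gene detection, principal-component pseudotime and stage
    assignment, pseudo-bulk cis-eQTL mapping with a kinship-aware linear
    mixed model, permutation-based gene-level error control with Storey
    q-values, phased gene-level allele-specific expression (ASE)
    quantification, regression tests for dynamic (pseudotime), cell-state
    (GxE) and higher-order (GxExE) allelic effects, co-expression module
    discovery by affinity propagation with per-cell module scores, and
    mixed-model discovery of differentiation-efficiency markers. A
    synthetic-data module generates pooled designs with known ground truth
    so that every stage has a parameter-recovery test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Matrix,
    lme4,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
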