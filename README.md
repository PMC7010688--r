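# scdyneqtl

Dynamic and cell-state eQTL mapping from pooled single-cell
differentiation experiments.

## The scientific problem

When induced pluripotent stem cell (iPSC) lines from many donors are
pooled, differentiated together (e.g. towards definitive endoderm) and
profiled by single-cell RNA-seq over several collection days, the
resulting data let us ask how genetic effects on gene expression change
along a differentiation trajectory and with the cellular environment.
`scdyneqtl` implements the full analysis chain for such designs, for
statistical geneticists and single-cell analysts:

1. **Preprocessing** — cell QC (counts, genes detected, top-100 fraction,
   mitochondrial fraction, mapping rate), log2(CPM+1) normalisation,
   expressed-gene filtering, and highly-variable-gene (HVG) detection
   against a mean–variance trend with batch correction.
2. **Trajectory** — pseudotime as the rescaled first principal component
   of the top HVGs, oriented by collection day; stage assignment
   (iPSC / mesendoderm / definitive endoderm) from day plus pseudotime
   windows; sliding pseudotime windows (25% of cells, stepping by 2.5%).
3. **cis-eQTL mapping** — pseudo-bulk aggregation over
   (donor, stage, experiment); a linear mixed model
   `y = Wc + xβ + u + e`, `u ~ N(0, σ_g² K)` with a realised kinship
   matrix `K = ZZ'/m` and expression principal components as covariates;
   likelihood-ratio tests per variant; gene-level multiplicity control by
   genotype permutation, `p_adj = (1 + #{perm min p ≤ obs}) / (n_perm+1)`;
   Storey q-values with smoothed π₀; cross-stage sharing and
   lead-switch detection (distinct leads with r² < 0.2).
4. **Allele-specific expression (ASE)** — phased SNP-level allelic counts
   are converted to haplotype (chrB) counts, summed to gene level over
   exonic heterozygous SNPs, and oriented to the chromosome carrying the
   alternative allele of each gene's eQTL variant, giving per-cell
   allelic fractions comparable across donors.
5. **Interaction tests** — per eQTL, Gaussian likelihood-ratio
   regressions of the allelic fraction: dynamic
   (`ASE ~ pseudo + pseudo²`, 2 df), cell-state GxE
   (`+ factor`, 1 df), and higher-order GxExE
   (`+ pseudo × factor`, 1 df); BH correction within each family;
   joint spectral clustering of expression and ASE dynamics profiles.
6. **Co-expression modules** — affinity propagation on gene–gene
   correlation over the top-expressed genes; per-cell module scores as
   cellular factors; Fisher-exact term enrichment against a
   user-supplied annotation.
7. **Differentiation efficiency** — per (donor, experiment) mean
   pseudotime of day-3 cells; mixed-model marker association
   `efficiency = marker + (1|experiment) + (1|donor)` with LRT and BH;
   replication in independent measurements; chromosome enrichment.

A first-class **synthetic-data module** generates pooled multi-donor
datasets with known ground truth — latent pseudotime coupled to
collection day, donor/batch random effects, static and
pseudotime-varying cis effects, latent cell-state factors modulating
allelic ratios via beta-binomial counts, and donor-specific
differentiation rates — so every stage has a parameter-recovery test
surface without downloading anything.

## Worked example

```r
library(scdyneqtl)

res <- run_pipeline(pipeline_config(seed = 2))

res$preprocess$log
#>         cells_in       cells_kept         genes_in  genes_expressed
#>             6000             5883              200              185

cor(res$trajectory$pt$pseudotime,
    res$dataset$truth$cells[res$trajectory$pt$cell, "pseudotime"])
#> [1] 0.9817717

sapply(res$eqtl$per_stage, function(s) length(s$egenes))
#>    iPSC mesendo defendo
#>     179     183     182

sum(res$interactions$dynamic$p_bh < 0.1)
#> [1] 163
```

The pipeline simulates 6,000 cells (30 donors, 6 pooled experiments,
4 days) with 200 genes; QC keeps 5,883 cells and 185 expressed genes.
The computed pseudotime correlates 0.98 with the latent trajectory, all
three stages recover most simulated eGenes at FDR 10% (every simulated
gene carries a cis effect), and 163 of the testable eQTL show dynamic
allelic effects along pseudotime — as injected by the generator.

Individual steps are exported (`simulate_dataset()`,
`qc_filter_cells()`, `normalize_log_cpm()`, `highly_variable_genes()`,
`compute_pseudotime()`, `assign_stages()`, `sliding_windows()`,
`map_cis_eqtl()`, `permutation_adjust()`, `storey_fdr()`,
`ase_gene_records()`, `test_dynamic()`, `test_factor()`,
`test_higher_order()`, `affinity_propagation_modules()`,
`module_scores()`, `differentiation_efficiency()`,
`test_marker_lmm()`, …); see the vignette in `vignettes/` for the
models, parameter choices and limitations.

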