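---
title: "Models and design choices in scdyneqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in scdyneqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`scdyneqtl` analyses pooled multi-donor single-cell RNA-seq of a
directed differentiation: several genotyped iPSC lines are differentiated
together in each experiment, cells are collected on successive days, and
the goal is to map cis genetic effects on expression — including effects
that change along the differentiation trajectory or with the cellular
environment. This vignette describes the statistical models, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the design choices made where the design was genuinely
open.

## Preprocessing

Cells pass QC when all five thresholds hold: total endogenous counts,
genes detected, fraction of counts in the top 100 genes, mitochondrial
fraction, and mapping rate (`qc_thresholds()`; full-scale defaults
50,000 / 5,000 / 0.90 / 0.15 / 0.60). A top-100 threshold of 1 disables
that check, which is necessary for matrices of ≤100 genes where the
fraction is identically one.

Normalisation is library-size CPM followed by log2(CPM+1). Pooled
deconvolution size factors are a common alternative for sparse data; we
use plain library-size factors because every downstream statistic
consumes log2(CPM+1) and the synthetic data are not sparse enough for
composition effects to matter. `normalize_log_cpm(size_factors=)`
accepts user-supplied factors (rescaled to preserve the CPM scale) when
deconvolution estimates are available.

The expressed-gene rule — raw count strictly above 100 in at least one
pre-QC cell *and* mean log2(CPM+1) strictly above 1 after QC — is
evaluated within each batch (experiment), and a gene is kept if it
passes in **any** batch (union semantics). Union rather than
intersection was chosen so that genes expressed only at one end of the
trajectory, which some experiments may not cover, are retained.

Highly variable genes: per-gene variances are computed on residuals
after removing per-experiment means (df = n − #experiments), a loess
trend of variance on mean (span 0.3, degree 1, symmetric family) is
taken as the technical component, and the biological variance is the
excess over the trend. Significance uses a scaled chi-square for the
variance ratio, `df · total/trend ~ χ²(df)`, BH-adjusted (default flag
at FDR 1%). The trend is clamped to a small positive floor so the ratio
is always defined.

## Pseudotime, stages, windows

Pseudotime is the first principal component of cells over the top
HVGs (default 500, capped at availability; genes centred and scaled —
scaling is a choice, it prevents a few high-variance genes from owning
PC1). The sign of a principal component is arbitrary, so PC1 is oriented
to correlate positively with the numeric day of collection (Spearman),
then linearly rescaled so the observed minimum is 0 and the maximum 1.

Stage assignment is a pure function of (day, pseudotime): mesendoderm
for day1/day2 cells with pseudotime in the closed interval [0.15, 0.5];
definitive endoderm for day2/day3 cells with pseudotime strictly above
0.7; every day0 cell is iPSC regardless of pseudotime; anything else is
unassigned. Boundary inclusivity (closed at 0.15/0.5, open at 0.7) and
the blanket day0→iPSC rule are our decisions where the verbal rule is
ambiguous; the exhaustive grid test in `test-trajectory.R` freezes them.

Sliding windows sort cells by pseudotime (ties broken by cell id for
bit-reproducibility) and emit windows of `round(frac·N)` cells whose
starts are `round(step·N)` ranks apart, while the window fits within N.
With frac 0.25 and step 0.025 this gives exactly 31 windows whenever N
is divisible by 40, and each interior cell lies in frac/step = 10
windows.

## cis-eQTL mapping

Expression is aggregated to pseudo-bulk means of log2(CPM+1) per
(donor, stage, experiment); a donor differentiated in two experiments
contributes two rows, which are genetically identical — exactly the
repeat structure the kinship random effect must absorb. The kinship is
`K = ZZ'/m` on per-variant standardised dosages; standardisation uses
the population-style denominator (divide by √mean squared deviation) so
a single variant yields unit diagonal. K is expanded to sample level by
indexing donors.

Per gene, variants with sample MAF strictly above 5% (computed on the
stratum's unique donors; all-heterozygous variants are excluded because
they carry no dosage variance) within ±250 kb of the gene body
(1-based, inclusive endpoints) are tested in

y = W c + x β + u + e,  u ~ N(0, σ_g² K),  e ~ N(0, σ_e² I)

with y the per-gene standardised phenotype, x the standardised dosage,
and W an intercept plus the leading expression PCs (default 10, capped
at n/4 so small strata keep residual degrees of freedom). After rotating
by the eigenvectors of K, the variance ratio δ = σ_e²/σ_g² is fitted
once per gene by maximum likelihood under the null (covariates only;
one-dimensional optimisation of log δ over ±10 nats) and reused across
the gene's variants — the score-test-style approximation standard in
large eQTL scans; each variant then reduces to weighted least squares
and a 1-df likelihood ratio `n·log(RSS0/RSS1)`. With K = I this
collapses exactly to the OLS likelihood-ratio test (verified to 1e-8 in
the tests). The lead variant minimises p, ties broken by distance to the
gene start and then position.

Gene-level multiplicity: donor labels of the genotypes are permuted
(default 1000 times) with expression, covariates and kinship held fixed;
the adjusted p is the empirical tail with a +1 pseudocount,
`(1 + #{perm min p ≤ observed min p})/(n_perm + 1)`, lower-bounded by
1/1001. A beta-approximation to the permutation null would be cheaper
but the empirical tail is exact and affordable at these problem sizes.
Across genes, Storey q-values are computed with π₀ estimated on the
λ grid 0.05…0.95 via a df-3 smoothing spline evaluated at the largest λ
(clamped to [1/m, 1]); with fewer than 50 p-values π₀ is fixed at 1.
Fixing π₀ = 1 makes the q-values exactly Benjamini–Hochberg.

Note one behaviour worth knowing: when nearly every gene is non-null
(as in the default simulation, where all genes carry an injected
effect), π₀ is estimated near 0.1 and genes with unremarkable adjusted
p can receive q < 0.1. That is Storey's method working as defined, not
a defect; lead-switch counts on such saturated simulations are
correspondingly generous.

Sharing between strata follows the nominal rule: a stratum-A lead is
shared if the same variant has p < 0.05 in stratum B with the same
effect sign. Lead switches are genes whose per-stratum leads are
distinct variants, each significant at FDR 10%, with all pairwise
r² < 0.2.

## Phased gene-level ASE

Allelic quantification proceeds in the field's haplotype-first order:
(i) per-cell SNP counts are converted from alternative-allele reads to
chrB reads using the donor's phase (phase "1|0": chrB = total − alt;
"0|1": chrB = alt); (ii) chrB and total reads are summed over all exonic
heterozygous SNPs of a gene in a cell; (iii) gene counts are oriented to
the chromosome carrying the alternative allele of the gene's eQTL
variant (phase "0|1": alt-chromosome = chrB; "1|0": total − chrB), and
only donors heterozygous at that variant contribute. The result is a
per-cell allelic fraction with a consistent meaning across donors.
Unphased or homozygous records are rejected with a reason; the minimum
total per record is 1 read (no deeper coverage filter). SNPs
overlapping several genes would count toward each; the simulator never
produces such SNPs.

Windows for ASE binning are defined over **all** cells; within a window
the statistics run over the member cells that have a record for the
given eQTL, so windows hold equal cell counts but unequal record counts
(SEM undefined below two records). Allele-resolved expression per window
is the binned mean ASE (± SEM) multiplied by the window's mean CPM over
the recorded cells.

## Interaction tests

Per-cell allelic fractions enter unweighted ordinary least squares —
no read-depth weights, matching the plain linear-model formulation; the
likelihood ratio uses the Gaussian likelihood with the residual variance
profiled out (`n·log(RSS0/RSS1)` against χ²). Three nested families,
each BH-corrected separately and never pooled:

* dynamic: `ASE ~ 1 + pseudo + pseudo²` vs intercept (2 df);
* cell-state (GxE): `… + factor` vs the dynamic model (1 df) — the
  pseudotime covariates are included whether or not the eQTL is dynamic;
* higher-order (GxExE): `… + pseudo×factor` vs the GxE model (1 df),
  run for **all** factors, not only those significant in the GxE family.

Tests require at least 50 records per eQTL. The asymptotic χ² reference
is slightly anti-conservative at n = 50–100 (Bartlett-type inflation of
a few percent), which the calibration tests bound rather than correct.

Dynamics profiles (per-eQTL window series of expression and ASE) are
z-scored per row, stacked into one matrix, and clustered jointly by
spectral clustering with affinity `(1 + r)/2` from the Pearson
correlation (a nonnegative monotone map of the correlation-based
dissimilarity), symmetric normalised Laplacian, and a seeded k-means
(nstart 25) on the row-normalised eigenvector embedding; k defaults
to 4.

## Co-expression modules and factors

The top 8,000 genes by mean log expression (all genes when fewer) are
clustered by affinity propagation with the gene–gene Pearson correlation
as similarity. The shared preference defaults to the median off-diagonal
similarity and damping to 0.9 (the algorithm's usual stable settings;
both overridable); a deterministic 1e-12-scale jitter removes exact-tie
degeneracies, and convergence means exemplars stable for 50 iterations.
A module's per-cell score is the z-score (across cells) of the mean of
per-gene z-scored log expression over members — "normalised mean
expression" made precise. Factor labels are not baked in: the
enrichment operation (one-sided Fisher exact tests against a
user-supplied gene–term table, BH at 10%) selects which modules
represent cell-cycle phases, respiration, sterol biosynthesis, etc. The
pipeline, lacking an annotation for synthetic data, takes the largest
modules as factors.

## Differentiation efficiency

Efficiency is the mean pseudotime of day-3 cells per
(donor, experiment), requiring at least 10 contributing cells (applied
to day 3 only). Marker association uses
`efficiency = marker + (1|experiment) + (1|donor)` fitted by ML
(`lme4`), with a 1-df LRT against the marker-free model and BH across
markers; genetic markers are 0/1/2 dosages of lead eQTL variants,
expression markers are iPSC-stage pseudo-bulk values. Singular fits
(zero variance components) are flagged, not discarded — at zero
variances the model reduces exactly to ordinary regression. Replication
is a simple regression on independent donor-level measurements with
nominal p < 0.05 and consistent sign. Chromosome enrichment is the
standard 2×2 Fisher test with fold =
(hits_on_chrom/hits)/(universe_on_chrom/universe); the X-enrichment
background keeps all tested genes (no Y exclusion, as the simulated
annotation has no Y).

## The synthetic-data generator

The generator emulates the pooled design: donors are drawn into
experiments at random (some lines appear in several experiments —
replicates — and possibly none), each pooled line contributes cells on
four days, and all randomness derives from one seed (bit-identical
re-runs). Latent pseudotime is Beta-distributed per day with increasing
means (shape pairs (2,12), (5,9), (9,6), (12,3)) — the observed
day–trajectory coupling without pretending to know a generative law —
shifted per donor on the logit scale (sd 0.5) to create reproducible
line-specific differentiation efficiencies. On the log2 scale a gene's
mean adds: baseline U(3,8); a trajectory loading ±U(2,4) on pseudotime
for 40% of genes (differentiation dominates total variance, as in the
real system); a loading of 0.6 on one of two latent N(0,1) cell-state
factors for two 25-gene modules; per-(gene,donor) and
per-(gene,experiment) effects (sd 0.3 each); a cis term
`(β_static + β_slope·pseudotime) · dosage` (defaults 0.5 and 0.5 per
allele, random sign per gene); and residual noise (sd 0.5). Counts are
negative binomial (dispersion 0.1) around the exponentiated mean times a
log-normal library factor. Allelic counts: each of a gene's two exonic
SNPs receives an equal rounded share of the gene's count in cells whose
donor is heterozygous at that SNP, split between haplotypes by a
beta-binomial (concentration 50; infinite = binomial) whose mean is
logistic in `β_static + β_slope·pseudotime + γ·factor` on the haplotype
carrying the causal variant's alternative allele. Phase is exact in the
truth — no phasing-error model, since phasing quality is upstream of
this package.

What the generator does **not** emulate — and hence what green tests do
not certify on real data: empty droplets/doublets, ambient RNA,
demultiplexing error, linkage disequilibrium between cis variants
(variants are drawn independently, so LD-driven lead instability is
absent), reference-mapping bias in allelic counts, zero-inflation beyond
the negative binomial, and realistic gene-gene correlation structure
outside the planted modules. The full-scale QC thresholds (50,000
counts etc.) are also meaningless at 200 simulated genes; the pipeline
configuration substitutes desk-scale thresholds (2,000 counts, 100
genes, top-100 check disabled) and documents them in
`pipeline_config()`.

Problem sizes used by the test-suite and the acceptance script — the
default design of 30 donors, 6 experiments × 5 pooled lines, 50
cells/line/day (6,000 cells), 200 genes × 5 cis SNPs; 1,000 null eQTL
for calibration; 200-gene permutation nulls at 1,000 permutations —
were chosen as the smallest sizes at which each property is
statistically decidable; all complete in a few minutes on one CPU.

## Numerical choices and degenerate inputs

* LRT statistics are clamped at 0 and RSS at machine epsilon.
* The variance-ratio search runs on log δ over [−10, 10]; at K = I any δ
  gives the same GLS fit, so the reduction to OLS is exact, not
  approximate.
* Variants collinear with the covariates (residual dosage variance
  ≤ 1e-10) are dropped from a gene's test set; genes with no testable
  variant are reported in `skipped`.
* Pseudotime on a zero-variance matrix, QC with missing mapping rates,
  empty p-value vectors, monomorphic variants in LD computation, and
  single-sex cohorts in the sex test all raise informative errors.
* Ties: window ranking by (pseudotime, cell id); lead variants by
  (p, distance to gene start, position); top-expressed genes by
  (mean, gene id).

## Known limitations

The permutation scheme is the exact empirical tail, not the
beta-approximation used by large scans — accurate but with p resolution
1/(n_perm+1). The LMM refits the variance ratio per gene but not per
variant (the exact refit would change p only when a variant explains an
appreciable share of σ_g²). Interaction tests treat per-cell fractions
as homoskedastic Gaussian observations; a beta-binomial GLMM would
weight depths properly at the cost of the simple nested-LRT structure.
Efficiency markers are tested one at a time — no joint or conditional
modelling.
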