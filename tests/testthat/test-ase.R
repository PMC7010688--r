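test_that("phase conversion maps alternative reads to chrB reads", {
  # one donor, two SNPs with opposite phase
  gt <- tiny_genotypes(hap1 = matrix(c(1L, 0L), 1), # v1 "1|0", v2 "0|1"
                       hap2 = matrix(c(0L, 1L), 1))
  counts <- data.frame(cell = c("c1", "c1"), snp = c("v1", "v2"),
                       ref_reads = c(7, 7), alt_reads = c(3, 3))
  out <- phase_to_haplotype_counts(counts, gt, c(c1 = "d1"))
  # phase "1|0": alt on chrA, chrB reads = total - alt = 7
  expect_equal(out$chrB_reads[out$snp == "v1"], 7)
  # phase "0|1": chrB reads = alt = 3
  expect_equal(out$chrB_reads[out$snp == "v2"], 3)
  # homozygous and empty records are rejected with a reason
  gt2 <- tiny_genotypes(hap1 = matrix(c(1L, 0L), 1),
                        hap2 = matrix(c(1L, 1L), 1))
  counts2 <- data.frame(cell = c("c1", "c1"), snp = c("v1", "v2"),
                        ref_reads = c(5, 0), alt_reads = c(5, 0))
  out2 <- phase_to_haplotype_counts(counts2, gt2, c(c1 = "d1"))
  expect_equal(nrow(out2), 0)
  expect_setequal(attr(out2, "rejected")$reason,
                  c("homozygous", "no_reads"))
})

test_that("SNP-to-gene aggregation is additive and order invariant", {
  gt <- tiny_genotypes(hap1 = matrix(c(0L, 0L), 1),
                       hap2 = matrix(c(1L, 1L), 1))
  counts <- data.frame(cell = "c1", snp = c("v1", "v2"),
                       ref_reads = c(2, 5), alt_reads = c(2, 5))
  hap <- phase_to_haplotype_counts(counts, gt, c(c1 = "d1"))
  agg <- aggregate_ase_to_gene(hap)
  expect_equal(agg$chrB_reads, 7)
  expect_equal(agg$total_reads, 14)
  # reversed order of records gives the same result
  agg2 <- aggregate_ase_to_gene(hap[2:1, ])
  expect_equal(agg, agg2, ignore_attr = TRUE)
  # single SNP passes through
  agg3 <- aggregate_ase_to_gene(hap[1, ])
  expect_equal(agg3$chrB_reads, 2)
})

test_that("orientation to the eQTL alternative allele follows the phase", {
  # gene-level counts chrB = 7 of 14; vary the eQTL variant's phase
  mk_gt <- function(e1, e2) tiny_genotypes(
    hap1 = matrix(c(0L, e1), 1), hap2 = matrix(c(1L, e2), 1),
    variants = data.frame(id = c("v1", "ve"), chrom = "chr1",
                          pos = c(100L, 200L), ref = "A", alt = "G",
                          gene = "geneA", exonic = c(TRUE, FALSE),
                          stringsAsFactors = FALSE))
  gc <- data.frame(cell = "c1", donor = "d1", gene = "geneA",
                   chrB_reads = 7, total_reads = 14)
  eq <- data.frame(gene = "geneA", variant = "ve")
  # eQTL phase "0|1": alt chromosome is chrB
  r1 <- orient_to_eqtl_alt(gc, mk_gt(0L, 1L), eq)
  expect_equal(r1$fraction, 0.5)
  expect_equal(r1$alt_chrom_reads, 7)
  # eQTL phase "1|0": alt chromosome is chrA = total - chrB
  gc2 <- gc; gc2$chrB_reads <- 10
  r2 <- orient_to_eqtl_alt(gc2, mk_gt(1L, 0L), eq)
  expect_equal(r2$alt_chrom_reads, 4)
  expect_equal(r2$fraction, 4 / 14)
  # homozygous donors at the eQTL variant yield no record
  r3 <- orient_to_eqtl_alt(gc, mk_gt(1L, 1L), eq)
  expect_equal(nrow(r3), 0)
})

test_that("the phased-ASE pipeline matches a brute-force single pass exactly", {
  for (seed in 1:20) {
    fx <- random_ase_fixture(seed)
    got <- ase_gene_records(fx$counts, fx$genotypes, fx$cell_donor,
                            fx$eqtl)
    want <- brute_force_ase(fx$counts, fx$genotypes, fx$cell_donor,
                            fx$eqtl)
    got <- got[order(got$cell, got$gene), ]
    expect_equal(got$alt_chrom_reads, want$alt_chrom_reads)
    expect_equal(got$total_reads, want$total_reads)
    expect_equal(got$fraction, want$fraction)
    expect_equal(got$cell, want$cell)
    expect_equal(got$gene, want$gene)
  }
})

test_that("orientation is involutive under a global phase flip", {
  fx <- random_ase_fixture(99)
  rec <- ase_gene_records(fx$counts, fx$genotypes, fx$cell_donor, fx$eqtl)
  flipped <- fx$genotypes
  flipped$hap1 <- fx$genotypes$hap2
  flipped$hap2 <- fx$genotypes$hap1
  rec2 <- ase_gene_records(fx$counts, flipped, fx$cell_donor, fx$eqtl)
  expect_equal(rec$fraction, rec2$fraction)
  expect_equal(rec$alt_chrom_reads, rec2$alt_chrom_reads)
})

test_that("simulated allelic shifts are recovered in the mean fraction", {
  cfg <- small_sim_config(seed = 21, beta_static = 0.4,
                          beta_dynamic_slope = 0, gxe_factor_effect = 0,
                          ase_overdispersion = Inf)
  ds <- simulate_dataset(cfg)
  cd <- setNames(ds$meta$donor, ds$meta$cell)
  eq <- data.frame(gene = ds$truth$genes$gene,
                   variant = ds$truth$genes$causal_variant)
  rec <- ase_gene_records(ds$allelic_counts, ds$genotypes, cd, eq)
  # per gene, mean fraction ~ plogis(signed beta)
  agg <- tapply(rec$fraction, rec$gene, mean)
  expected <- plogis(ds$truth$genes$beta_static[
    match(names(agg), ds$truth$genes$gene)])
  expect_lt(mean(abs(agg - expected)), 0.03)
})

test_that("pseudotime binning matches a brute-force group-by", {
  set.seed(30)
  n <- 80
  pt <- data.frame(cell = sprintf("c%02d", 1:n),
                   pseudotime = runif(n))
  w <- sliding_windows(pt, frac = 0.5, step = 0.25)
  rec <- data.frame(cell = sample(pt$cell, 60),
                    donor = "d1", gene = "gA", variant = "v1",
                    alt_chrom_reads = 1,
                    total_reads = 2, fraction = runif(60))
  binned <- bin_ase_pseudotime(rec, w)
  for (i in seq_len(nrow(binned))) {
    cells <- intersect(w$members[[binned$window[i]]], rec$cell)
    vals <- rec$fraction[match(cells, rec$cell)]
    expect_equal(binned$n[i], length(vals))
    expect_equal(binned$mean_ase[i], mean(vals))
    if (length(vals) > 1) {
      expect_equal(binned$sem[i], sd(vals) / sqrt(length(vals)))
    } else {
      expect_true(is.na(binned$sem[i]))
    }
  }
  # constant fractions give constant means with zero spread
  rec2 <- rec; rec2$fraction <- 0.5
  b2 <- bin_ase_pseudotime(rec2, w)
  expect_true(all(b2$mean_ase == 0.5))
  expect_true(all(b2$sd_ase[b2$n > 1] == 0))
})

test_that("allele-resolved expression splits the mean CPM by the binned ASE", {
  pt <- data.frame(cell = sprintf("c%d", 1:8),
                   pseudotime = seq(0, 1, length.out = 8))
  w <- sliding_windows(pt, frac = 0.5, step = 0.5)
  rec <- data.frame(cell = pt$cell, donor = "d1", gene = "gA",
                    variant = "v1", alt_chrom_reads = 3, total_reads = 5,
                    fraction = c(rep(0.6, 4), rep(0.5, 4)))
  binned <- bin_ase_pseudotime(rec, w)
  cpm <- matrix(100, 1, 8, dimnames = list("gA", pt$cell))
  dyn <- allelic_expression_dynamics(binned, cpm, rec, w)
  expect_equal(dyn$expr_alt[1], 60)
  expect_equal(dyn$expr_ref[1], 40)
  expect_equal(dyn$expr_alt[2], 50)
  # conservation: the two alleles always sum to the mean CPM
  expect_equal(dyn$expr_alt + dyn$expr_ref, dyn$mean_cpm)
})
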