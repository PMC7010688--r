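# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk.

small_sim_config <- function(seed = 1L, ...) {
  args <- list(n_donors = 12, n_experiments = 4, lines_per_pool = 4,
               cells_per_donor_day = 15, n_genes = 40, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}

small_qc <- function() qc_thresholds(min_endogenous_counts = 300,
                                     min_genes_detected = 20,
                                     max_top100_fraction = 1,
                                     max_mt_fraction = 0.5,
                                     min_mapping_rate = 0.6)

# Hand-built phased genotypes for unit tests: explicit haplotypes.
tiny_genotypes <- function(hap1, hap2, donors = NULL, variants = NULL) {
  if (is.null(donors)) donors <- sprintf("d%d", seq_len(nrow(hap1)))
  ids <- if (is.null(variants)) sprintf("v%d", seq_len(ncol(hap1))) else
    variants$id
  dimnames(hap1) <- dimnames(hap2) <- list(donors, ids)
  if (is.null(variants))
    variants <- data.frame(id = ids, chrom = "chr1",
                           pos = seq_len(ncol(hap1)) * 1000L,
                           ref = "A", alt = "G",
                           gene = "geneA", exonic = TRUE,
                           stringsAsFactors = FALSE)
  structure(list(hap1 = hap1, hap2 = hap2, variants = variants,
                 donors = donors), class = "phased_genotypes")
}

# Independent single-pass brute-force oracle for the full phased-ASE
# pipeline: for every (cell, gene) it walks the SNP count rows once and
# accumulates reads from the chromosome carrying the alternative allele of
# the gene's eQTL variant, using only first-principles phase logic.
brute_force_ase <- function(snp_counts, genotypes, cell_donor, eqtl) {
  acc <- list()
  for (i in seq_len(nrow(snp_counts))) {
    row <- snp_counts[i, ]
    donor <- cell_donor[[row$cell]]
    s1 <- genotypes$hap1[donor, row$snp]
    s2 <- genotypes$hap2[donor, row$snp]
    total <- row$ref_reads + row$alt_reads
    if (s1 == s2 || total <= 0) next                    # snp not informative
    gene <- genotypes$variants$gene[genotypes$variants$id == row$snp]
    ev <- eqtl$variant[eqtl$gene == gene]
    if (!length(ev)) next
    e1 <- genotypes$hap1[donor, ev]
    e2 <- genotypes$hap2[donor, ev]
    if (e1 == e2) next                                  # donor hom at eQTL
    # reads from the haplotype carrying the eQTL ALT allele: if this SNP's
    # alt allele sits on the same haplotype as the eQTL alt allele, those
    # are the alt reads of the SNP, otherwise the ref reads.
    same_hap <- (e1 == 1 && s1 == 1) || (e2 == 1 && s2 == 1)
    reads <- if (same_hap) row$alt_reads else row$ref_reads
    key <- paste(row$cell, gene)
    if (is.null(acc[[key]]))
      acc[[key]] <- list(cell = row$cell, gene = gene, variant = ev,
                         alt = 0, total = 0)
    acc[[key]]$alt <- acc[[key]]$alt + reads
    acc[[key]]$total <- acc[[key]]$total + total
  }
  if (!length(acc))
    return(data.frame(cell = character(), gene = character(),
                      alt_chrom_reads = numeric(), total_reads = numeric(),
                      fraction = numeric()))
  out <- do.call(rbind, lapply(acc, function(a)
    data.frame(cell = a$cell, gene = a$gene, variant = a$variant,
               alt_chrom_reads = a$alt, total_reads = a$total,
               fraction = a$alt / a$total, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$cell, out$gene), , drop = FALSE]
}

# Random small ASE fixture: random phased genotypes over a few donors,
# genes with 2 exonic SNPs each, random counts; used to compare the
# package pipeline against the brute-force oracle.
random_ase_fixture <- function(seed, n_donors = 4, n_genes = 3,
                               n_cells = 10) {
  set.seed(seed)
  donors <- sprintf("d%d", seq_len(n_donors))
  genes <- sprintf("g%d", seq_len(n_genes))
  # per gene: 2 exonic SNPs + 1 eQTL variant
  ids <- as.vector(vapply(genes, function(g)
    paste0(g, c("_s1", "_s2", "_e")), character(3)))
  n_var <- length(ids)
  hap1 <- matrix(rbinom(n_donors * n_var, 1, 0.5), n_donors,
                 dimnames = list(donors, ids))
  hap2 <- matrix(rbinom(n_donors * n_var, 1, 0.5), n_donors,
                 dimnames = list(donors, ids))
  variants <- data.frame(id = ids, chrom = "chr1",
                         pos = seq_len(n_var) * 100L, ref = "A", alt = "G",
                         gene = rep(genes, each = 3),
                         exonic = rep(c(TRUE, TRUE, FALSE), n_genes),
                         stringsAsFactors = FALSE)
  gt <- structure(list(hap1 = hap1, hap2 = hap2, variants = variants,
                       donors = donors), class = "phased_genotypes")
  cells <- sprintf("c%02d", seq_len(n_cells))
  cell_donor <- setNames(sample(donors, n_cells, replace = TRUE), cells)
  snp_ids <- ids[variants$exonic]
  counts <- expand.grid(cell = cells, snp = snp_ids,
                        stringsAsFactors = FALSE)
  counts$ref_reads <- rpois(nrow(counts), 4)
  counts$alt_reads <- rpois(nrow(counts), 4)
  counts <- counts[sample(nrow(counts), round(0.8 * nrow(counts))), ]
  eqtl <- data.frame(gene = genes, variant = paste0(genes, "_e"),
                     stringsAsFactors = FALSE)
  list(genotypes = gt, cell_donor = cell_donor, counts = counts,
       eqtl = eqtl)
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
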