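#' Simulation configuration for pooled differentiation experiments
#'
#' Defines the generative conditions for a pooled multi-donor iPSC
#' differentiation dataset: several cell lines are pooled per experiment,
#' cells are collected on four days, a latent differentiation trajectory
#' (pseudotime) drives a block of genes, and cis-regulatory variants act on
#' expression both statically and with pseudotime-varying strength, as well
#' as on allelic ratios through latent cell-state factors.
#'
#' @param n_donors number of genotyped donors (cell lines).
#' @param lines_per_pool number of lines pooled in each experiment (4-6).
#' @param n_experiments number of pooled differentiation experiments; lines
#'   are drawn at random per experiment so some donors appear in several
#'   experiments (replicates) and some in none.
#' @param days ordered collection-day labels.
#' @param cells_per_donor_day cells retained per (pooled line, day).
#' @param n_genes number of genes.
#' @param n_cis_snps_per_gene candidate cis variants per gene, placed within
#'   the cis window of the gene body.
#' @param maf_range range of generating allele frequencies.
#' @param beta_static static cis effect magnitude, log2 expression per
#'   alternative allele; sign randomised per gene.
#' @param beta_dynamic_slope change of the cis effect per unit pseudotime
#'   (log2 per allele per pseudotime).
#' @param gxe_factor_effect shift of the allelic-ratio linear predictor per
#'   unit cell-state factor (logit scale).
#' @param donor_sd,batch_sd,residual_sd standard deviations (log2 scale) of
#'   per-(gene,donor) effects, per-(gene,experiment) effects, and residual
#'   cell-level noise.
#' @param differentiation_rate_sd standard deviation (logit scale) of the
#'   donor-level shift of latent pseudotime, giving lines reproducibly
#'   different differentiation efficiencies.
#' @param nb_dispersion negative-binomial overdispersion of counts
#'   (`size = 1/nb_dispersion`).
#' @param ase_overdispersion beta-binomial concentration of allelic counts;
#'   `Inf` gives binomial splitting.
#' @param prop_trajectory_genes fraction of genes loading on the latent
#'   trajectory.
#' @param module_size number of genes in each of the two latent cell-state
#'   factor modules.
#' @param seed integer seed; fully determines all outputs.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(n_donors = 30,
                              lines_per_pool = 5,
                              n_experiments = 6,
                              days = paste0("day", 0:3),
                              cells_per_donor_day = 50,
                              n_genes = 200,
                              n_cis_snps_per_gene = 5,
                              maf_range = c(0.05, 0.5),
                              beta_static = 0.5,
                              beta_dynamic_slope = 0.5,
                              gxe_factor_effect = 0.5,
                              donor_sd = 0.3,
                              batch_sd = 0.3,
                              residual_sd = 0.5,
                              differentiation_rate_sd = 0.5,
                              nb_dispersion = 0.1,
                              ase_overdispersion = 50,
                              prop_trajectory_genes = 0.4,
                              module_size = 25,
                              seed = 1L) {
  cfg <- list(n_donors = as.integer(n_donors),
              lines_per_pool = as.integer(lines_per_pool),
              n_experiments = as.integer(n_experiments),
              days = as.character(days),
              cells_per_donor_day = as.integer(cells_per_donor_day),
              n_genes = as.integer(n_genes),
              n_cis_snps_per_gene = as.integer(n_cis_snps_per_gene),
              maf_range = as.numeric(maf_range),
              beta_static = beta_static,
              beta_dynamic_slope = beta_dynamic_slope,
              gxe_factor_effect = gxe_factor_effect,
              donor_sd = donor_sd, batch_sd = batch_sd,
              residual_sd = residual_sd,
              differentiation_rate_sd = differentiation_rate_sd,
              nb_dispersion = nb_dispersion,
              ase_overdispersion = ase_overdispersion,
              prop_trajectory_genes = prop_trajectory_genes,
              module_size = as.integer(module_size),
              seed = as.integer(seed))
  counts <- c("n_donors", "lines_per_pool", "n_experiments",
              "cells_per_donor_day", "n_genes", "n_cis_snps_per_gene")
  for (f in counts) {
    if (cfg[[f]] < 1L) stop("'", f, "' must be a positive count")
  }
  if (cfg$lines_per_pool > cfg$n_donors)
    stop("'lines_per_pool' cannot exceed 'n_donors'")
  if (length(cfg$maf_range) != 2L || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2])
    stop("'maf_range' must be a nondecreasing pair within (0, 0.5]")
  sds <- c(cfg$donor_sd, cfg$batch_sd, cfg$residual_sd)
  if (any(sds < 0)) stop("standard deviations must be nonnegative")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Pooled differentiation simulation config\n")
  cat(sprintf("  %d donors, %d experiments x %d lines/pool, %d days, %d cells/line/day\n",
              x$n_donors, x$n_experiments, x$lines_per_pool,
              length(x$days), x$cells_per_donor_day))
  cat(sprintf("  %d genes x %d cis SNPs; beta_static=%.2f, slope=%.2f, gxe=%.2f; seed=%d\n",
              x$n_genes, x$n_cis_snps_per_gene, x$beta_static,
              x$beta_dynamic_slope, x$gxe_factor_effect, x$seed))
  invisible(x)
}

# Deterministic gene annotation: genes laid out 1 Mb apart on two
# chromosomes, 20 kb bodies; a handful of genes flagged mitochondrial so the
# QC path (MT fraction) is exercised.
gene_annotation_from_config <- function(config) {
  n <- config$n_genes
  chrom <- ifelse(seq_len(n) %% 2L == 0L, "chr2", "chr1")
  idx <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  start <- 1e6 * idx
  data.frame(gene = sprintf("gene%03d", seq_len(n)),
             chrom = chrom,
             start = as.integer(start),
             end = as.integer(start + 2e4),
             mt = seq_len(n) > n - 3L,  # last 3 genes "mitochondrial"
             stringsAsFactors = FALSE)
}

#' Simulate phased donor genotypes for cis windows
#'
#' For every gene, `n_cis_snps_per_gene` biallelic variants are placed at
#' random positions within 250 kb of the gene body, and two haplotype
#' alleles per donor are drawn independently at the variant's generating
#' allele frequency (common variants; frequencies from `maf_range`).
#'
#' @param config a [simulation_config()].
#' @return object of class `phased_genotypes`: a list with `hap1`, `hap2`
#'   (donors x variants 0/1 matrices; hap1 = chrA, hap2 = chrB of the phased
#'   genotype chrA|chrB), `variants` (data frame with id, chrom, pos, ref,
#'   alt, gene, exonic flag, generating and realized allele frequency),
#'   `donors`, and the gene annotation used.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  annot <- gene_annotation_from_config(config)
  k <- config$n_cis_snps_per_gene
  n_var <- config$n_genes * k
  donors <- sprintf("donor%02d", seq_len(config$n_donors))

  offset <- sample(-250000:250000, n_var, replace = TRUE)
  gene_idx <- rep(seq_len(config$n_genes), each = k)
  pos <- pmax(1L, annot$start[gene_idx] + as.integer(offset))
  af <- runif(n_var, config$maf_range[1], config$maf_range[2])
  hap1 <- matrix(rbinom(config$n_donors * n_var, 1L, rep(af, each = config$n_donors)),
                 nrow = config$n_donors)
  hap2 <- matrix(rbinom(config$n_donors * n_var, 1L, rep(af, each = config$n_donors)),
                 nrow = config$n_donors)
  ids <- sprintf("snp_%s_%d", annot$gene[gene_idx], rep(seq_len(k), config$n_genes))
  dimnames(hap1) <- dimnames(hap2) <- list(donors, ids)
  # First two SNPs of each gene are exonic (they receive allelic reads).
  exonic <- rep(seq_len(k), config$n_genes) <= min(2L, k)
  variants <- data.frame(id = ids,
                         chrom = annot$chrom[gene_idx],
                         pos = pos,
                         ref = "A", alt = "G",
                         gene = annot$gene[gene_idx],
                         exonic = exonic,
                         af = af,
                         maf_realized = NA_real_,
                         stringsAsFactors = FALSE)
  f <- colMeans(hap1 + hap2) / 2
  variants$maf_realized <- pmin(f, 1 - f)
  structure(list(hap1 = hap1, hap2 = hap2, variants = variants,
                 donors = donors, annotation = annot),
            class = "phased_genotypes")
}

#' Allele dosage matrix from phased genotypes
#'
#' @param genotypes a `phased_genotypes` object.
#' @return donors x variants matrix of alternative-allele dosages (0/1/2).
#' @export
genotype_dosage <- function(genotypes) {
  genotypes$hap1 + genotypes$hap2
}

#' @export
print.phased_genotypes <- function(x, ...) {
  cat(sprintf("Phased genotypes: %d donors x %d variants (%d genes)\n",
              length(x$donors), nrow(x$variants),
              length(unique(x$variants$gene))))
  invisible(x)
}

# Day-specific Beta laws for latent pseudotime: means increase with day,
# mirroring the observed coupling between collection day and trajectory
# position without a prescribed generative law.
.pt_beta_shapes <- list(day0 = c(2, 12), day1 = c(5, 9),
                        day2 = c(9, 6), day3 = c(12, 3))

#' Simulate single-cell expression for a pooled differentiation experiment
#'
#' Cells carry a latent pseudotime drawn from day-specific Beta
#' distributions with increasing means. On the log2 scale, a gene's mean in
#' a cell is baseline + trajectory loading x pseudotime + module loading x
#' latent factor + per-(gene,donor) effect + per-(gene,experiment) effect +
#' cis term `(beta_static + beta_dynamic_slope * pseudotime) * dosage` +
#' residual noise; counts are negative binomial around the exponentiated
#' mean scaled by a per-cell library factor.
#'
#' @param config a [simulation_config()].
#' @param genotypes output of [simulate_genotypes()] for the same config.
#' @return list with `counts` (genes x cells integer matrix), `meta`
#'   (per-cell data frame: cell, donor, line, experiment, day, mapping_rate,
#'   pass_7aad, donor_assigned), `truth` (list: `genes` data frame with the
#'   causal variant and signed effect sizes per gene, `cells` data frame
#'   with latent pseudotime and factor values), and the gene `annotation`.
#' @export
simulate_cells <- function(config, genotypes) {
  stopifnot(inherits(config, "sim_config"),
            inherits(genotypes, "phased_genotypes"))
  if (length(genotypes$donors) != config$n_donors ||
      nrow(genotypes$variants) != config$n_genes * config$n_cis_snps_per_gene)
    stop("genotypes do not match the simulation config")
  set.seed(config$seed + 1L)
  annot <- genotypes$annotation
  n_genes <- config$n_genes
  genes <- annot$gene

  # Pool assignment: each experiment samples lines_per_pool donors.
  pools <- lapply(seq_len(config$n_experiments), function(e)
    sort(sample(config$n_donors, config$lines_per_pool)))

  slots <- do.call(rbind, lapply(seq_along(pools), function(e)
    data.frame(experiment = sprintf("expt%d", e),
               donor = genotypes$donors[pools[[e]]],
               stringsAsFactors = FALSE)))
  cells <- do.call(rbind, lapply(config$days, function(d) {
    x <- slots[rep(seq_len(nrow(slots)), each = config$cells_per_donor_day), ]
    x$day <- d
    x
  }))
  n_cells <- nrow(cells)
  cells$cell <- sprintf("cell%05d", seq_len(n_cells))
  rownames(cells) <- cells$cell

  # Latent per-cell state. Donor-level rate shifts (logit scale) make some
  # lines differentiate reproducibly faster than others.
  rate <- setNames(rnorm(config$n_donors, 0, config$differentiation_rate_sd),
                   genotypes$donors)
  shp <- do.call(rbind, .pt_beta_shapes[cells$day])
  pt <- plogis(stats::qlogis(rbeta(n_cells, shp[, 1], shp[, 2])) +
                 rate[cells$donor])
  fac <- matrix(rnorm(n_cells * 2L), ncol = 2L,
                dimnames = list(cells$cell, c("factor1", "factor2")))

  # Gene architecture.
  # Differentiation is the dominant axis of variation: trajectory loadings
  # exceed the cell-state module loadings in variance contributed.
  n_traj <- round(config$prop_trajectory_genes * n_genes)
  traj_load <- numeric(n_genes)
  traj_load[seq_len(n_traj)] <-
    sample(c(-1, 1), n_traj, replace = TRUE) * runif(n_traj, 2, 4)
  module <- integer(n_genes)
  m <- config$module_size
  mod_genes <- (n_traj + 1L):min(n_genes, n_traj + 2L * m)
  module[mod_genes] <- rep(1:2, each = m, length.out = length(mod_genes))
  mod_load <- ifelse(module > 0L, 0.6, 0)

  causal <- sprintf("snp_%s_%d", genes,
                    sample(config$n_cis_snps_per_gene, n_genes, replace = TRUE))
  sgn <- sample(c(-1, 1), n_genes, replace = TRUE)
  beta_static <- sgn * config$beta_static
  beta_slope <- sgn * config$beta_dynamic_slope
  gxe_factor <- sample(1:2, n_genes, replace = TRUE)
  gxe_effect <- sample(c(-1, 1), n_genes, replace = TRUE) * config$gxe_factor_effect
  baseline <- runif(n_genes, 3, 8)

  donor_eff <- matrix(rnorm(n_genes * config$n_donors, 0, config$donor_sd),
                      nrow = n_genes,
                      dimnames = list(genes, genotypes$donors))
  expt_ids <- sprintf("expt%d", seq_len(config$n_experiments))
  batch_eff <- matrix(rnorm(n_genes * config$n_experiments, 0, config$batch_sd),
                      nrow = n_genes, dimnames = list(genes, expt_ids))

  dos <- genotype_dosage(genotypes)[cells$donor, causal, drop = FALSE]  # cells x genes
  fac_term <- matrix(0, n_genes, n_cells)
  midx <- which(module > 0L)
  if (length(midx))
    fac_term[midx, ] <- mod_load[midx] * t(fac[, module[midx], drop = FALSE])
  mu_log2 <- matrix(baseline, n_genes, n_cells) +
    outer(traj_load, pt) +
    fac_term +
    donor_eff[, cells$donor, drop = FALSE] +
    batch_eff[, cells$experiment, drop = FALSE] +
    t(dos) * (beta_static + outer(beta_slope, pt)) +
    matrix(rnorm(n_genes * n_cells, 0, config$residual_sd), n_genes)

  lib <- rlnorm(n_cells, 0, 0.2)
  mu <- 2^mu_log2 * rep(lib, each = n_genes)
  counts <- matrix(rnbinom(n_genes * n_cells, mu = mu,
                           size = 1 / config$nb_dispersion),
                   nrow = n_genes, dimnames = list(genes, cells$cell))

  # QC covariates: most cells clean, a small fraction with poor mapping.
  mapping_rate <- runif(n_cells, 0.7, 0.95)
  low <- runif(n_cells) < 0.02
  mapping_rate[low] <- runif(sum(low), 0.3, 0.55)
  donor_sex <- setNames(sample(c("female", "male"), config$n_donors,
                               replace = TRUE), genotypes$donors)
  meta <- data.frame(cell = cells$cell, donor = cells$donor,
                     line = cells$donor, experiment = cells$experiment,
                     day = cells$day, sex = unname(donor_sex[cells$donor]),
                     mapping_rate = mapping_rate,
                     pass_7aad = TRUE, donor_assigned = TRUE,
                     stringsAsFactors = FALSE, row.names = cells$cell)

  truth_genes <- data.frame(gene = genes, causal_variant = causal,
                            beta_static = beta_static,
                            beta_dynamic_slope = beta_slope,
                            gxe_factor = paste0("factor", gxe_factor),
                            gxe_effect = gxe_effect,
                            trajectory_loading = traj_load,
                            module = module, baseline = baseline,
                            stringsAsFactors = FALSE)
  truth_cells <- data.frame(cell = cells$cell, pseudotime = pt,
                            factor1 = fac[, 1], factor2 = fac[, 2],
                            stringsAsFactors = FALSE, row.names = cells$cell)
  truth_donors <- data.frame(donor = genotypes$donors,
                             differentiation_rate = unname(rate),
                             sex = unname(donor_sex),
                             stringsAsFactors = FALSE)
  list(counts = counts, meta = meta,
       truth = list(genes = truth_genes, cells = truth_cells,
                    donors = truth_donors),
       annotation = annot)
}

#' Simulate per-cell allelic read counts at exonic heterozygous SNPs
#'
#' For each exonic SNP at which a cell's donor is heterozygous, the SNP
#' receives an equal rounded share of the gene's total count in that cell.
#' Reads are split between the two haplotypes by a beta-binomial whose mean
#' is logistic in `beta_static + beta_dynamic_slope * pseudotime +
#' gxe_effect * factor` on the haplotype carrying the alternative allele of
#' the gene's causal cis variant. Donors homozygous at an exonic SNP emit no
#' record for that SNP.
#'
#' @param truth ground truth from [simulate_cells()].
#' @param genotypes matching `phased_genotypes`.
#' @param expr the `counts` matrix from the same simulation.
#' @param config the [simulation_config()] used.
#' @return data frame of SNP-level allelic counts: cell, snp, chrom, pos,
#'   gene, ref_reads, alt_reads, total_reads.
#' @export
simulate_allelic_counts <- function(truth, genotypes, expr, config) {
  stopifnot(inherits(genotypes, "phased_genotypes"))
  set.seed(config$seed + 2L)
  v <- genotypes$variants
  exonic <- v[v$exonic, , drop = FALSE]
  tg <- truth$genes
  tc <- truth$cells
  cells <- colnames(expr)
  out <- vector("list", nrow(exonic))
  conc <- config$ase_overdispersion
  meta_donor <- truth$cell_donor
  if (is.null(meta_donor)) stop("truth lacks cell->donor map; use simulate_dataset()")
  for (i in seq_len(nrow(exonic))) {
    snp <- exonic$id[i]
    gene <- exonic$gene[i]
    g <- tg[tg$gene == gene, ]
    cz <- genotypes$hap1[, g$causal_variant]  # chrA carries alt?
    cz2 <- genotypes$hap2[, g$causal_variant]
    het_causal <- cz != cz2
    s1 <- genotypes$hap1[, snp]; s2 <- genotypes$hap2[, snp]
    het_snp <- s1 != s2
    don <- meta_donor[cells]
    use <- het_snp[don]
    cc <- cells[use]
    if (!length(cc)) { out[[i]] <- NULL; next }
    d <- don[use]
    # share of the gene count across this gene's het exonic SNPs per donor
    snps_g <- exonic$id[exonic$gene == gene]
    n_het_d <- rowSums(genotypes$hap1[d, snps_g, drop = FALSE] !=
                       genotypes$hap2[d, snps_g, drop = FALSE])
    total <- round(expr[gene, cc] / pmax(1L, n_het_d))
    pt <- tc[cc, "pseudotime"]
    fv <- tc[cc, g$gxe_factor]
    eta <- g$beta_static + g$beta_dynamic_slope * pt + g$gxe_effect * fv
    # allelic fraction on the haplotype carrying the causal ALT allele; for
    # donors homozygous at the causal variant both haplotypes are exchangeable
    p_alt_hap <- ifelse(het_causal[d], plogis(eta), 0.5)
    p_cell <- if (is.finite(conc)) {
      rbeta(length(cc), p_alt_hap * conc, (1 - p_alt_hap) * conc)
    } else p_alt_hap
    reads_alt_hap <- rbinom(length(cc), total, p_cell)
    # which haplotype carries the causal alt allele (hap1 = chrA)
    causal_on_hap1 <- cz[d] == 1L
    hap1_reads <- ifelse(causal_on_hap1 | !het_causal[d],
                         reads_alt_hap, total - reads_alt_hap)
    # translate haplotype reads to this SNP's ref/alt via its own phase
    alt_reads <- ifelse(s1[d] == 1L, hap1_reads, total - hap1_reads)
    keep <- total > 0
    if (!any(keep)) { out[[i]] <- NULL; next }
    out[[i]] <- data.frame(cell = cc[keep], snp = snp,
                           chrom = exonic$chrom[i], pos = exonic$pos[i],
                           gene = gene,
                           ref_reads = (total - alt_reads)[keep],
                           alt_reads = alt_reads[keep],
                           total_reads = total[keep],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res[order(res$cell, res$snp), , drop = FALSE]
}

#' Simulate a complete pooled differentiation dataset
#'
#' Convenience wrapper running [simulate_genotypes()], [simulate_cells()]
#' and [simulate_allelic_counts()] under one configuration.
#'
#' @param config a [simulation_config()].
#' @return list with `config`, `genotypes`, `counts`, `meta`, `annotation`,
#'   `truth` and `allelic_counts`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  genotypes <- simulate_genotypes(config)
  sim <- simulate_cells(config, genotypes)
  truth <- sim$truth
  truth$cell_donor <- setNames(sim$meta$donor, sim$meta$cell)
  ase <- simulate_allelic_counts(truth, genotypes, sim$counts, config)
  list(config = config, genotypes = genotypes, counts = sim$counts,
       meta = sim$meta, annotation = sim$annotation, truth = truth,
       allelic_counts = ase)
}
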