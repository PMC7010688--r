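#' Convert SNP-level allelic counts to haplotype (chrB) counts
#'
#' Using each donor's known phase (chrA|chrB; 0 = reference,
#' 1 = alternative), per-cell alternative-allele read counts are converted
#' to reads from the chrB haplotype: for phase "0|1" the alternative allele
#' lies on chrB so chrB reads equal the alternative reads; for phase "1|0"
#' chrB reads are `total - alt`. Records at SNPs where the donor is
#' homozygous, or with zero total reads, are rejected.
#'
#' @param snp_counts data frame with cell, snp, ref_reads, alt_reads (and
#'   optionally total_reads), as produced by [simulate_allelic_counts()] or
#'   read from a counting tool.
#' @param genotypes a `phased_genotypes` object (hap1 = chrA, hap2 = chrB).
#' @param cell_donor named character vector mapping cell id to donor.
#' @return data frame: cell, donor, snp, gene, chrB_reads, total_reads.
#'   Rejected records (with a `reason`) are attached as attribute
#'   `"rejected"`.
#' @export
phase_to_haplotype_counts <- function(snp_counts, genotypes, cell_donor) {
  d <- cell_donor[snp_counts$cell]
  if (anyNA(d))
    stop("cells without donor assignment: ",
         paste(head(unique(snp_counts$cell[is.na(d)]), 5L), collapse = ", "))
  j <- match(snp_counts$snp, colnames(genotypes$hap1))
  if (anyNA(j))
    stop("SNP(s) absent from genotypes: ",
         paste(head(unique(snp_counts$snp[is.na(j)]), 5L), collapse = ", "))
  ij <- cbind(match(d, rownames(genotypes$hap1)), j)
  h1 <- genotypes$hap1[ij]
  h2 <- genotypes$hap2[ij]
  total <- if (!is.null(snp_counts$total_reads)) snp_counts$total_reads else
    snp_counts$ref_reads + snp_counts$alt_reads
  reason <- rep(NA_character_, nrow(snp_counts))
  if (!is.null(genotypes$unphased))
    reason[genotypes$unphased[ij]] <- "unphased"
  reason[is.na(reason) & (is.na(h1) | is.na(h2))] <- "missing_genotype"
  reason[is.na(reason) & h1 == h2] <- "homozygous"
  reason[is.na(reason) & total <= 0] <- "no_reads"
  ok <- is.na(reason)
  chrB <- ifelse(h2 == 1L, snp_counts$alt_reads,
                 total - snp_counts$alt_reads)
  gene <- if (!is.null(snp_counts$gene)) snp_counts$gene else
    genotypes$variants$gene[match(snp_counts$snp, genotypes$variants$id)]
  out <- data.frame(cell = snp_counts$cell[ok], donor = unname(d[ok]),
                    snp = snp_counts$snp[ok], gene = gene[ok],
                    chrB_reads = chrB[ok], total_reads = total[ok],
                    stringsAsFactors = FALSE)
  rej <- data.frame(cell = snp_counts$cell[!ok], snp = snp_counts$snp[!ok],
                    reason = reason[!ok], stringsAsFactors = FALSE)
  attr(out, "rejected") <- rej
  out
}

#' Aggregate haplotype counts from SNP level to gene level
#'
#' Sums chrB reads and total reads over all exonic heterozygous SNPs of
#' each gene within each cell. SNPs mapped to no gene are dropped.
#'
#' @param hap_counts output of [phase_to_haplotype_counts()].
#' @return data frame: cell, donor, gene, chrB_reads, total_reads.
#' @export
aggregate_ase_to_gene <- function(hap_counts) {
  hc <- hap_counts[!is.na(hap_counts$gene), , drop = FALSE]
  key <- paste(hc$cell, hc$donor, hc$gene, sep = "\r")
  chrB <- rowsum(hc$chrB_reads, key)
  tot <- rowsum(hc$total_reads, key)
  parts <- do.call(rbind, strsplit(rownames(chrB), "\r", fixed = TRUE))
  out <- data.frame(cell = parts[, 1], donor = parts[, 2],
                    gene = parts[, 3], chrB_reads = as.numeric(chrB),
                    total_reads = as.numeric(tot), stringsAsFactors = FALSE)
  out[order(out$cell, out$gene), , drop = FALSE]
}

#' Orient gene-level haplotype counts to the eQTL alternative allele
#'
#' For each (gene, eQTL variant) pair, gene-level chrB reads are converted
#' to reads from the chromosome carrying the alternative allele of the
#' eQTL variant: with eQTL phase "0|1" the alternative allele is on chrB so
#' the alt-chromosome reads equal the chrB reads; with phase "1|0" they are
#' `total - chrB`. Cells from donors not heterozygous at the eQTL variant
#' are dropped, so the allelic fraction is comparable across donors.
#'
#' @param gene_counts output of [aggregate_ase_to_gene()].
#' @param genotypes a `phased_genotypes` object.
#' @param eqtl data frame with gene and variant columns (one eQTL variant
#'   per gene, e.g. lead variants).
#' @return data frame of ASE records: cell, donor, gene, variant,
#'   alt_chrom_reads, total_reads, fraction.
#' @export
orient_to_eqtl_alt <- function(gene_counts, genotypes, eqtl) {
  j <- match(gene_counts$gene, eqtl$gene)
  gc <- gene_counts[!is.na(j), , drop = FALSE]
  variant <- eqtl$variant[j[!is.na(j)]]
  vj <- match(variant, colnames(genotypes$hap1))
  if (anyNA(vj))
    stop("eQTL variant(s) absent from genotypes: ",
         paste(head(unique(variant[is.na(vj)]), 5L), collapse = ", "))
  ij <- cbind(match(gc$donor, rownames(genotypes$hap1)), vj)
  h1 <- genotypes$hap1[ij]
  h2 <- genotypes$hap2[ij]
  het <- h1 != h2
  gc <- gc[het, , drop = FALSE]
  variant <- variant[het]
  alt_on_chrB <- h2[het] == 1L
  alt_reads <- ifelse(alt_on_chrB, gc$chrB_reads,
                      gc$total_reads - gc$chrB_reads)
  out <- data.frame(cell = gc$cell, donor = gc$donor, gene = gc$gene,
                    variant = variant, alt_chrom_reads = alt_reads,
                    total_reads = gc$total_reads,
                    fraction = alt_reads / gc$total_reads,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Gene-level phased ASE records relative to eQTL variants
#'
#' Convenience composition of [phase_to_haplotype_counts()],
#' [aggregate_ase_to_gene()] and [orient_to_eqtl_alt()].
#'
#' @inheritParams phase_to_haplotype_counts
#' @inheritParams orient_to_eqtl_alt
#' @param min_total minimum total gene-level reads per record (default 1).
#' @return data frame of ASE records (see [orient_to_eqtl_alt()]).
#' @export
ase_gene_records <- function(snp_counts, genotypes, cell_donor, eqtl,
                             min_total = 1) {
  hap <- phase_to_haplotype_counts(snp_counts, genotypes, cell_donor)
  gene <- aggregate_ase_to_gene(hap)
  rec <- orient_to_eqtl_alt(gene, genotypes, eqtl)
  rec[rec$total_reads >= min_total, , drop = FALSE]
}

#' Bin ASE records along pseudotime
#'
#' Windows are taken over all cells; within each window, statistics are
#' computed over the member cells that carry an ASE record for the given
#' eQTL (windows hold equal cell counts but unequal record counts). The
#' SEM is undefined (NA) for windows with fewer than two records.
#'
#' @param records ASE records from [ase_gene_records()].
#' @param windows a `window_set` from [sliding_windows()].
#' @return data frame: gene, variant, window, center, n, mean_ase, sd_ase,
#'   sem.
#' @export
bin_ase_pseudotime <- function(records, windows) {
  stopifnot(inherits(windows, "window_set"))
  eqtls <- unique(records[, c("gene", "variant")])
  out <- vector("list", nrow(eqtls) * nrow(windows$windows))
  k <- 0L
  for (i in seq_len(nrow(eqtls))) {
    r <- records[records$gene == eqtls$gene[i] &
                 records$variant == eqtls$variant[i], , drop = FALSE]
    fr <- setNames(r$fraction, r$cell)
    for (w in seq_len(nrow(windows$windows))) {
      x <- fr[names(fr) %in% windows$members[[w]]]
      k <- k + 1L
      nw <- length(x)
      out[[k]] <- data.frame(gene = eqtls$gene[i],
                             variant = eqtls$variant[i],
                             window = windows$windows$window[w],
                             center = windows$windows$center[w],
                             n = nw,
                             mean_ase = if (nw) mean(x) else NA_real_,
                             sd_ase = if (nw > 1L) sd(x) else NA_real_,
                             sem = if (nw > 1L) sd(x) / sqrt(nw) else NA_real_,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Allele-resolved expression dynamics along pseudotime
#'
#' Per window, the mean CPM of the gene over heterozygous-donor cells is
#' split between the two chromosomes using the binned mean ASE: the
#' alt-chromosome expression is `mean ASE x mean CPM` and the other
#' chromosome gets the remainder; SEM bands are scaled the same way.
#'
#' @param binned output of [bin_ase_pseudotime()].
#' @param cpm genes x cells matrix of CPM values (not log).
#' @param records the ASE records (define the heterozygous cells per eQTL).
#' @param windows the `window_set` used for binning.
#' @return `binned` with added columns mean_cpm, expr_alt, expr_ref,
#'   expr_alt_lo/hi (mean +/- SEM scaled).
#' @export
allelic_expression_dynamics <- function(binned, cpm, records, windows) {
  het_cells <- split(records$cell, paste(records$gene, records$variant))
  key <- paste(binned$gene, binned$variant)
  mean_cpm <- rep(NA_real_, nrow(binned))
  for (i in seq_len(nrow(binned))) {
    cells <- intersect(windows$members[[binned$window[i]]],
                       het_cells[[key[i]]])
    if (length(cells))
      mean_cpm[i] <- mean(cpm[binned$gene[i], cells])
  }
  binned$mean_cpm <- mean_cpm
  binned$expr_alt <- binned$mean_ase * mean_cpm
  binned$expr_ref <- (1 - binned$mean_ase) * mean_cpm
  binned$expr_alt_lo <- (binned$mean_ase - binned$sem) * mean_cpm
  binned$expr_alt_hi <- (binned$mean_ase + binned$sem) * mean_cpm
  binned
}
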