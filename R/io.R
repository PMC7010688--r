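#' Write phased genotypes as VCF
#'
#' Minimal VCF 4.2 with phased GT entries (chrA|chrB) for all donors.
#'
#' @param genotypes a `phased_genotypes` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", genotypes$donors),
                     collapse = "\t")), con)
  gt <- matrix(paste0(t(genotypes$hap1), "|", t(genotypes$hap2)),
               nrow = nrow(v))
  ord <- order(v$chrom, v$pos, v$id)
  body <- cbind(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".",
                "GT", gt)[ord, , drop = FALSE]
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read phased genotypes from a VCF
#'
#' Parses the GT field of a VCF; phased entries ("0|1") populate both
#' haplotypes, unphased heterozygous entries ("0/1") are flagged and get NA
#' haplotypes (their dosage is still usable for eQTL mapping, but they are
#' excluded from the phased ASE path). Multi-allelic records are rejected.
#'
#' @param path VCF file path.
#' @return a `phased_genotypes` object; the per-entry `unphased` logical
#'   matrix is attached as element `unphased`.
#' @export
read_phased_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- t(fix)       # single-record VCF
    gt <- vcfR::extract.gt(vcf, element = "GT")
    if (is.null(dim(gt)))
      gt <- matrix(gt, nrow = nrow(fix), dimnames = list(fix[, "ID"],
                                                         names(gt)))
  } else {
    lines <- readLines(path)
    hdr <- grep("^#CHROM", lines)
    if (!length(hdr)) stop("malformed VCF: no #CHROM header line")
    cols <- strsplit(lines[hdr], "\t")[[1]]
    body <- lines[-seq_len(hdr)]
    body <- body[nzchar(body)]
    fields <- strsplit(body, "\t")
    nf <- lengths(fields)
    if (any(nf != length(cols)))
      stop("malformed VCF line ", hdr + which(nf != length(cols))[1],
           ": expected ", length(cols), " fields")
    tab <- do.call(rbind, fields)
    fix <- tab[, 1:5, drop = FALSE]
    colnames(fix) <- c("CHROM", "POS", "ID", "REF", "ALT")
    gt <- sub(":.*", "", tab[, -(1:9), drop = FALSE])
    dimnames(gt) <- list(fix[, "ID"], cols[-(1:9)])
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    stop("multi-allelic record(s) not supported: ",
         paste(head(fix[multi, "ID"], 3L), collapse = ", "))
  donors <- colnames(gt)
  split_gt <- function(x, sep) {
    out <- matrix(NA_integer_, nrow(gt), 2L)
    ok <- grepl(sep, x, fixed = TRUE)
    parts <- strsplit(x[ok], sep, fixed = TRUE)
    out[ok, 1] <- as.integer(vapply(parts, `[`, character(1), 1L))
    out[ok, 2] <- as.integer(vapply(parts, `[`, character(1), 2L))
    out
  }
  n_var <- nrow(gt)
  hap1 <- hap2 <- matrix(NA_integer_, length(donors), n_var,
                         dimnames = list(donors, fix[, "ID"]))
  unphased <- matrix(FALSE, length(donors), n_var,
                     dimnames = list(donors, fix[, "ID"]))
  for (d in seq_along(donors)) {
    g <- gt[, d]
    ph <- split_gt(g, "|")
    un <- split_gt(g, "/")
    hap1[d, ] <- ifelse(!is.na(ph[, 1]), ph[, 1], un[, 1])
    hap2[d, ] <- ifelse(!is.na(ph[, 2]), ph[, 2], un[, 2])
    unphased[d, ] <- is.na(ph[, 1]) & !is.na(un[, 1])
  }
  variants <- data.frame(id = fix[, "ID"], chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  f <- colMeans(hap1 + hap2, na.rm = TRUE) / 2
  variants$maf_realized <- pmin(f, 1 - f)
  structure(list(hap1 = hap1, hap2 = hap2, variants = variants,
                 donors = donors, unphased = unphased),
            class = "phased_genotypes")
}

#' Read a count matrix from MatrixMarket or TSV
#'
#' @param path MTX file (with `genes` and `cells` name files) or a TSV with
#'   gene ids in the first column and cell ids in the header.
#' @param genes_path,cells_path name files accompanying an MTX file
#'   (defaults: `<path>.genes.txt`, `<path>.cells.txt`).
#' @return genes x cells numeric matrix with dimnames.
#' @export
read_counts <- function(path, genes_path = NULL, cells_path = NULL) {
  if (!file.size(path)) stop("empty counts file: ", path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    if (is.null(genes_path)) genes_path <- paste0(path, ".genes.txt")
    if (is.null(cells_path)) cells_path <- paste0(path, ".cells.txt")
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop("MTX dimensions do not match the name files")
    dimnames(m) <- list(genes, cells)
    m
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                      check.names = FALSE)
    as.matrix(tab)
  }
}

# TSV writer with a provenance header comment.
write_tsv_provenance <- function(df, path, seed = NULL, params = NULL) {
  hdr <- sprintf("# scdyneqtl %s%s%s",
                 as.character(utils::packageVersion("scdyneqtl")),
                 if (!is.null(seed)) paste0(" seed=", seed) else "",
                 if (!is.null(params)) paste0(" ", params) else "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(df, digits = 6, trim = TRUE, scientific = NA),
              con, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  invisible(path)
}

#' Write a simulated dataset to plain-text fixture files
#'
#' Emits a phased VCF, MatrixMarket counts with gene/cell name files,
#' metadata, gene annotation, allelic counts and ground-truth TSVs, plus a
#' manifest with MD5 checksums of every file.
#'
#' @param dataset output of [simulate_dataset()].
#' @param out_dir output directory (created if needed).
#' @return data frame manifest (file, md5), also written as
#'   `manifest.tsv`.
#' @export
write_fixture <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  p <- function(f) file.path(out_dir, f)
  write_phased_vcf(dataset$genotypes, p("genotypes.vcf"))
  Matrix::writeMM(Matrix::Matrix(dataset$counts, sparse = TRUE),
                  p("counts.mtx"))
  writeLines(rownames(dataset$counts), p("counts.mtx.genes.txt"))
  writeLines(colnames(dataset$counts), p("counts.mtx.cells.txt"))
  write.table(dataset$meta, p("metadata.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(dataset$annotation, p("annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$allelic_counts, p("allelic_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$truth$genes, p("truth_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$truth$cells, p("truth_cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$truth$donors, p("truth_donors.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  files <- c("genotypes.vcf", "counts.mtx", "counts.mtx.genes.txt",
             "counts.mtx.cells.txt", "metadata.tsv", "annotation.tsv",
             "allelic_counts.tsv", "truth_genes.tsv", "truth_cells.tsv",
             "truth_donors.tsv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir,
                                                              files))),
                         stringsAsFactors = FALSE)
  write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest
}

#' Read back a fixture directory written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return list with genotypes, counts, meta, annotation, allelic_counts,
#'   truth.
#' @export
read_fixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  rt <- function(f) read.table(p(f), header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  list(genotypes = read_phased_vcf(p("genotypes.vcf")),
       counts = read_counts(p("counts.mtx")),
       meta = rt("metadata.tsv"),
       annotation = rt("annotation.tsv"),
       allelic_counts = rt("allelic_counts.tsv"),
       truth = list(genes = rt("truth_genes.tsv"),
                    cells = rt("truth_cells.tsv"),
                    donors = rt("truth_donors.tsv")))
}
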