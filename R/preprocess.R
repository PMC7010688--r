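#' Cell quality-control thresholds
#'
#' Defaults follow standard full-length scRNA-seq QC for this kind of
#' experiment: at least 50,000 counts from endogenous genes, at least 5,000
#' genes detected, less than 90% of counts in the 100 highest-expressed
#' genes, less than 15% mitochondrial reads, and a mapping rate of at least
#' 60%. Synthetic desk-scale data use looser values (see vignette).
#'
#' @param min_endogenous_counts minimum total counts per cell.
#' @param min_genes_detected minimum genes with nonzero count.
#' @param max_top100_fraction maximum fraction of counts in the top 100
#'   genes.
#' @param max_mt_fraction maximum fraction of mitochondrial counts.
#' @param min_mapping_rate minimum alignment rate.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_endogenous_counts = 50000,
                          min_genes_detected = 5000,
                          max_top100_fraction = 0.90,
                          max_mt_fraction = 0.15,
                          min_mapping_rate = 0.60) {
  fr <- c(max_top100_fraction, max_mt_fraction, min_mapping_rate)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (min_endogenous_counts <= 0 || min_genes_detected <= 0)
    stop("count thresholds must be positive")
  structure(list(min_endogenous_counts = min_endogenous_counts,
                 min_genes_detected = min_genes_detected,
                 max_top100_fraction = max_top100_fraction,
                 max_mt_fraction = max_mt_fraction,
                 min_mapping_rate = min_mapping_rate),
            class = "qc_thresholds")
}

#' Filter cells on quality-control thresholds
#'
#' A cell is kept iff all five thresholds pass: endogenous counts, genes
#' detected, top-100 count fraction, mitochondrial fraction, mapping rate.
#' Dead-cell (7AAD) and donor-assignment filters are honoured when the
#' metadata carries `pass_7aad` / `donor_assigned` columns.
#'
#' @param counts genes x cells count matrix.
#' @param meta per-cell metadata with a `mapping_rate` column.
#' @param thresholds a [qc_thresholds()] object.
#' @param mt_genes character vector of mitochondrial gene ids (may be
#'   empty).
#' @return character vector of kept cell ids, in input order.
#' @export
qc_filter_cells <- function(counts, meta, thresholds = qc_thresholds(),
                            mt_genes = character()) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 0L) return(character())
  cells <- colnames(counts)
  if (is.null(meta$mapping_rate))
    stop("metadata lacks a 'mapping_rate' column")
  mr <- meta$mapping_rate[match(cells, meta$cell)]
  if (anyNA(mr))
    stop("missing mapping rate for cell(s): ",
         paste(head(cells[is.na(mr)], 5L), collapse = ", "))
  total <- colSums(counts)
  detected <- colSums(counts > 0)
  top100 <- apply(counts, 2L, function(x) {
    s <- sum(x)
    if (s == 0) return(1)
    sum(sort(x, decreasing = TRUE)[seq_len(min(100L, length(x)))]) / s
  })
  mt_frac <- if (length(mt_genes)) {
    colSums(counts[rownames(counts) %in% mt_genes, , drop = FALSE]) /
      pmax(total, 1)
  } else rep(0, length(cells))
  keep <- total >= thresholds$min_endogenous_counts &
    detected >= thresholds$min_genes_detected &
    # a threshold of 1 disables the top-100 check (matrices with <= 100
    # genes have fraction identically 1)
    (top100 < thresholds$max_top100_fraction |
       thresholds$max_top100_fraction >= 1) &
    mt_frac < thresholds$max_mt_fraction &
    mr >= thresholds$min_mapping_rate
  if (!is.null(meta$pass_7aad))
    keep <- keep & meta$pass_7aad[match(cells, meta$cell)]
  if (!is.null(meta$donor_assigned))
    keep <- keep & meta$donor_assigned[match(cells, meta$cell)]
  cells[keep]
}

#' Normalise counts to log2(CPM + 1)
#'
#' Library-size (counts-per-million) normalisation followed by the
#' log2(CPM + 1) transform used by all downstream statistics. User-supplied
#' size factors (e.g. pooled-deconvolution factors) may replace library
#' sizes; they are rescaled to preserve the CPM scale.
#'
#' @param counts genes x cells matrix of nonnegative counts.
#' @param size_factors optional positive per-cell size factors.
#' @return genes x cells matrix of log2(CPM + 1) values.
#' @export
normalize_log_cpm <- function(counts, size_factors = NULL) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("cell(s) with zero total counts: ",
         paste(head(colnames(counts)[lib == 0], 5L), collapse = ", "))
  if (is.null(size_factors)) {
    sf <- lib / 1e6
  } else {
    if (length(size_factors) != ncol(counts) || any(size_factors <= 0))
      stop("'size_factors' must be positive, one per cell")
    sf <- size_factors / mean(size_factors) * mean(lib) / 1e6
  }
  log2(sweep(counts, 2L, sf, "/") + 1)
}

#' Expressed-gene filter
#'
#' Within each batch (experiment), a gene is expressed iff (i) its raw
#' count exceeds `min_count` in at least one pre-QC cell of the batch and
#' (ii) its mean log2(CPM+1) over the batch's post-QC cells exceeds
#' `min_mean_log`. The union of per-batch expressed sets is returned.
#'
#' @param counts_pre_qc genes x cells raw counts before QC.
#' @param logcpm_post_qc genes x cells log2(CPM+1) matrix of QC-passing
#'   cells (same gene universe).
#' @param meta metadata covering all cells of both matrices, with a batch
#'   column.
#' @param batch_col metadata column defining batches.
#' @param min_count strict raw-count threshold (default 100).
#' @param min_mean_log strict mean log-expression threshold (default 1).
#' @return character vector of expressed gene ids (input order).
#' @export
filter_expressed_genes <- function(counts_pre_qc, logcpm_post_qc, meta,
                                   batch_col = "experiment",
                                   min_count = 100, min_mean_log = 1) {
  counts_pre_qc <- as.matrix(counts_pre_qc)
  logcpm_post_qc <- as.matrix(logcpm_post_qc)
  if (!identical(rownames(counts_pre_qc), rownames(logcpm_post_qc)))
    stop("matrices must share the same gene universe")
  batch_of <- setNames(as.character(meta[[batch_col]]), meta$cell)
  batches <- unique(batch_of[colnames(counts_pre_qc)])
  keep <- rep(FALSE, nrow(counts_pre_qc))
  for (b in batches) {
    pre <- counts_pre_qc[, batch_of[colnames(counts_pre_qc)] == b,
                         drop = FALSE]
    post <- logcpm_post_qc[, batch_of[colnames(logcpm_post_qc)] == b,
                           drop = FALSE]
    if (ncol(post) == 0L) next
    pass <- apply(pre, 1L, max) > min_count & rowMeans(post) > min_mean_log
    keep <- keep | pass
  }
  rownames(counts_pre_qc)[keep]
}

#' Highly variable genes against a mean-variance trend
#'
#' Per-gene variances are computed on residuals after removing batch
#' (experiment) means, so experiment-specific offsets do not inflate
#' variability. A local-regression trend of variance on mean expression
#' captures the technical mean-variance relation; the biological variance
#' is the excess over the trend and significance comes from a scaled
#' chi-square test of the variance ratio, BH-adjusted.
#'
#' @param logcpm genes x cells log2(CPM+1) matrix.
#' @param meta per-cell metadata; batch correction uses `batch_col` when at
#'   least two levels are present.
#' @param fdr flagging threshold on BH-adjusted p-values (default 0.01).
#' @param batch_col metadata column naming the experiment/batch.
#' @param span loess span of the mean-variance trend.
#' @return data frame (one row per gene, ordered by decreasing biological
#'   variance): gene, mean, total, tech, bio, p, fdr, hvg flag.
#' @export
highly_variable_genes <- function(logcpm, meta, fdr = 0.01,
                                  batch_col = "experiment", span = 0.3) {
  logcpm <- as.matrix(logcpm)
  if (nrow(logcpm) < 10L)
    stop("need at least 10 genes to fit a mean-variance trend")
  batch <- as.factor(meta[[batch_col]][match(colnames(logcpm), meta$cell)])
  n <- ncol(logcpm)
  if (nlevels(batch) >= 2L) {
    # residual variance after removing per-batch gene means
    centered <- logcpm
    for (b in levels(batch)) {
      idx <- which(batch == b)
      centered[, idx] <- logcpm[, idx, drop = FALSE] -
        rowMeans(logcpm[, idx, drop = FALSE])
    }
    df_resid <- n - nlevels(batch)
  } else {
    centered <- logcpm - rowMeans(logcpm)
    df_resid <- n - 1L
  }
  total <- rowSums(centered^2) / df_resid
  mu <- rowMeans(logcpm)
  fit <- loess(total ~ mu, span = span, degree = 1,
               family = "symmetric")
  tech <- pmax(predict(fit, mu), 1e-8)
  bio <- total - tech
  ratio <- total / tech
  p <- pchisq(df_resid * ratio, df = df_resid, lower.tail = FALSE)
  adj <- p.adjust(p, "BH")
  out <- data.frame(gene = rownames(logcpm), mean = mu, total = total,
                    tech = tech, bio = bio, p = p, fdr = adj,
                    hvg = adj < fdr, stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(-out$bio, out$gene), , drop = FALSE]
}
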