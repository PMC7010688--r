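#' Select the highest-expressed genes
#'
#' Genes ranked by mean log2(CPM+1) across all cells; ties broken by gene
#' id. When fewer than `n` genes are available all genes are returned with
#' a warning.
#'
#' @param logcpm genes x cells matrix.
#' @param n number of genes to keep (default 8000).
#' @return character vector of gene ids, highest mean expression first.
#' @export
select_top_expressed <- function(logcpm, n = 8000) {
  logcpm <- as.matrix(logcpm)
  if (n > nrow(logcpm)) {
    warning("only ", nrow(logcpm), " genes available; returning all")
    n <- nrow(logcpm)
  }
  mu <- rowMeans(logcpm)
  ord <- order(-mu, rownames(logcpm))
  rownames(logcpm)[ord][seq_len(n)]
}

#' Co-expression modules by affinity propagation
#'
#' Affinity propagation over the gene-gene Pearson correlation (computed
#' across cells) as the similarity; the shared preference defaults to the
#' median off-diagonal similarity. Message passing uses damping and stops
#' when exemplars are stable for `convits` iterations. Every clustered gene
#' belongs to exactly one module and each module's exemplar is a member.
#'
#' @param logcpm genes x cells matrix restricted to the genes to cluster
#'   (e.g. [select_top_expressed()]).
#' @param preference shared preference (diagonal of the similarity);
#'   default median off-diagonal similarity.
#' @param damping damping factor in [0.5, 1) (default 0.9).
#' @param maxit maximum message-passing iterations.
#' @param convits iterations of stable exemplars required for convergence.
#' @param seed seed for the tiny symmetry-breaking noise added to the
#'   similarities.
#' @return object of class `coexpression_modules`: list with `modules`
#'   (data frame: gene, module, exemplar) and `exemplars`.
#' @export
affinity_propagation_modules <- function(logcpm, preference = NULL,
                                         damping = 0.9, maxit = 1000,
                                         convits = 50, seed = 1L) {
  x <- as.matrix(logcpm)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 genes to cluster")
  S <- suppressWarnings(cor(t(x)))
  S[is.na(S)] <- 0
  if (is.null(preference))
    preference <- median(S[upper.tri(S)])
  diag(S) <- preference
  # tiny jitter removes degeneracies from exactly tied similarities
  set.seed(seed)
  S <- S + matrix(rnorm(n * n), n, n) * 1e-12 *
    (max(S) - min(S) + .Machine$double.eps)

  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  lam <- damping
  stable <- 0L
  ex_prev <- NULL
  for (it in seq_len(maxit)) {
    # responsibilities
    AS <- A + S
    mx1 <- apply(AS, 1L, max)
    w1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), w1)] <- -Inf
    mx2 <- apply(AS2, 1L, max)
    Rmax <- matrix(mx1, n, n)
    Rmax[cbind(seq_len(n), w1)] <- mx2
    R <- lam * R + (1 - lam) * (S - Rmax)
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- lam * A + (1 - lam) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, ex_prev) && length(ex)) {
      stable <- stable + 1L
      if (stable >= convits) break
    } else stable <- 0L
    ex_prev <- ex
  }
  ex <- which(diag(A) + diag(R) > 0)
  if (!length(ex) || stable < convits)
    stop("affinity propagation did not converge; increase damping or maxit")
  assign <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  assign[ex] <- ex
  ids <- match(assign, sort(unique(assign)))
  genes <- rownames(x)
  modules <- data.frame(gene = genes,
                        module = sprintf("module%02d", ids),
                        exemplar = genes[assign], stringsAsFactors = FALSE)
  structure(list(modules = modules,
                 exemplars = genes[sort(unique(assign))],
                 preference = preference, iterations = it),
            class = "coexpression_modules")
}

#' @export
print.coexpression_modules <- function(x, ...) {
  cat(sprintf("Co-expression modules: %d genes in %d modules (preference %.3f)\n",
              nrow(x$modules), length(x$exemplars), x$preference))
  invisible(x)
}

#' Per-cell module scores (cellular factors)
#'
#' A module's score in a cell is the mean over member genes of the per-gene
#' z-scored log expression, itself z-scored across cells, giving a
#' unitless quantitative measure of the module's activity per cell.
#'
#' @param logcpm genes x cells matrix.
#' @param modules a `coexpression_modules` object (or a data frame with
#'   gene and module columns).
#' @param module_ids modules to score (default all).
#' @return cells x modules matrix of scores (mean 0, sd 1 per column).
#' @export
module_scores <- function(logcpm, modules, module_ids = NULL) {
  logcpm <- as.matrix(logcpm)
  mod <- if (inherits(modules, "coexpression_modules")) modules$modules
         else modules
  if (is.null(module_ids)) module_ids <- unique(mod$module)
  z <- zscore_rows(logcpm)
  dimnames(z) <- dimnames(logcpm)
  out <- sapply(module_ids, function(mid) {
    members <- intersect(mod$gene[mod$module == mid], rownames(z))
    if (!length(members))
      stop("module ", mid, " has no members in the expression matrix")
    zscore(colMeans(z[members, , drop = FALSE]))
  })
  out <- matrix(out, ncol = length(module_ids),
                dimnames = list(colnames(logcpm), module_ids))
  out
}

#' Annotation-term enrichment of a module (Fisher's exact test)
#'
#' One-sided Fisher's exact test of each term's annotated genes inside
#' versus outside the module, over a user-supplied universe (typically all
#' clustered genes). The odds ratio is the sample 2x2 cross-product ratio;
#' a zero cell yields `Inf`.
#'
#' @param module_genes character vector of member genes.
#' @param annotation data frame mapping gene to term.
#' @param universe character vector of background genes (must contain the
#'   module).
#' @param fdr BH threshold for the `significant` flags.
#' @return data frame per term: term, n_module, n_universe, odds_ratio, p,
#'   p_bh, significant. Terms with no annotated gene in the universe are
#'   skipped.
#' @export
term_enrichment <- function(module_genes, annotation, universe, fdr = 0.10) {
  annotation <- annotation[annotation$gene %in% universe, , drop = FALSE]
  module_genes <- intersect(module_genes, universe)
  terms <- unique(annotation$term)
  out <- lapply(terms, function(tm) {
    ann <- unique(annotation$gene[annotation$term == tm])
    a <- length(intersect(module_genes, ann))
    b <- length(module_genes) - a
    cc <- length(setdiff(intersect(universe, ann), module_genes))
    d <- length(universe) - length(module_genes) - cc
    tab <- matrix(c(a, b, cc, d), 2L)
    p <- fisher.test(tab, alternative = "greater")$p.value
    or <- if (b * cc == 0) Inf else (a * d) / (b * cc)
    data.frame(term = tm, n_module = a, n_universe = a + cc,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$p_bh <- p.adjust(res$p, "BH")
  res$significant <- res$p_bh < fdr
  rownames(res) <- NULL
  res[order(res$p), , drop = FALSE]
}
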