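# Per-eQTL design assembly shared by the three ASE test families.
.ase_design <- function(records, pt, factors = NULL) {
  p <- pt$pseudotime[match(records$cell, pt$cell)]
  d <- data.frame(y = records$fraction, pseudo = p, pseudo2 = p^2)
  if (!is.null(factors)) {
    fm <- as.matrix(factors[match(records$cell, rownames(factors)), ,
                            drop = FALSE])
    d <- cbind(d, fm)
  }
  d[complete.cases(d), , drop = FALSE]
}

.split_eqtl <- function(records) {
  split(records, paste(records$gene, records$variant, sep = "\r"))
}

.eqtl_ids <- function(keys) {
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  data.frame(gene = parts[, 1], variant = parts[, 2],
             stringsAsFactors = FALSE)
}

#' Test for dynamic allelic effects (pseudotime dependence of ASE)
#'
#' Per eQTL, the per-cell allelic fractions are jointly tested for linear
#' and quadratic dependence on pseudotime: the full model
#' `ASE ~ 1 + pseudo + pseudo^2` is compared against an intercept-only null
#' by a 2-df Gaussian likelihood ratio test on unweighted least squares.
#' eQTL with fewer than `min_cells` records are skipped.
#'
#' @param records ASE records from [ase_gene_records()].
#' @param pt pseudotime data frame ([compute_pseudotime()]).
#' @param min_cells minimum number of ASE records per eQTL (default 50).
#' @return data frame per tested eQTL: gene, variant, n, stat, df, p,
#'   coefficients (intercept, linear, quadratic) and residual variance;
#'   skipped eQTL are listed in the `"skipped"` attribute.
#' @export
test_dynamic <- function(records, pt, min_cells = 50) {
  by_eqtl <- .split_eqtl(records)
  keep <- vapply(by_eqtl, nrow, integer(1)) >= min_cells
  out <- lapply(by_eqtl[keep], function(r) {
    d <- .ase_design(r, pt)
    n <- nrow(d)
    X1 <- cbind(1, d$pseudo, d$pseudo2)
    f1 <- ols_rss(X1, d$y)
    f0 <- ols_rss(cbind(rep(1, n)), d$y)
    lt <- lrt_gaussian(f0$rss, f1$rss, n, df = 2L)
    data.frame(n = n, stat = lt$stat, df = 2L, p = lt$p,
               b0 = f1$coef[1], b_pseudo = f1$coef[2],
               b_pseudo2 = f1$coef[3], resid_var = f1$rss / n)
  })
  res <- cbind(.eqtl_ids(names(by_eqtl)[keep]), do.call(rbind, out))
  rownames(res) <- NULL
  attr(res, "skipped") <- .eqtl_ids(names(by_eqtl)[!keep])
  res
}

#' Test for cell-state (GxE) allelic effects
#'
#' Per eQTL and per cellular factor, adds the factor to the quadratic
#' pseudotime model and performs a 1-df likelihood ratio test:
#' `ASE ~ 1 + pseudo + pseudo^2 + factor` against
#' `ASE ~ 1 + pseudo + pseudo^2`. The pseudotime covariates are always
#' included, whether or not the eQTL is dynamic.
#'
#' @param records ASE records.
#' @param pt pseudotime data frame.
#' @param factors cells x factors matrix/data frame of factor scores, with
#'   cell ids as row names (e.g. from [module_scores()]).
#' @param min_cells minimum records per eQTL (default 50).
#' @return data frame per (eQTL, factor): gene, variant, factor, n, stat,
#'   df, p, b_factor. Factors constant across an eQTL's cells are reported
#'   with NA statistics.
#' @export
test_factor <- function(records, pt, factors, min_cells = 50) {
  factors <- as.matrix(factors)
  by_eqtl <- .split_eqtl(records)
  keep <- vapply(by_eqtl, nrow, integer(1)) >= min_cells
  fnames <- colnames(factors)
  out <- lapply(by_eqtl[keep], function(r) {
    d <- .ase_design(r, pt, factors)
    n <- nrow(d)
    X0 <- cbind(1, d$pseudo, d$pseudo2)
    f0 <- ols_rss(X0, d$y)
    do.call(rbind, lapply(fnames, function(fn) {
      fv <- d[[fn]]
      if (sd(fv) == 0)
        return(data.frame(factor = fn, n = n, stat = NA_real_, df = 1L,
                          p = NA_real_, b_factor = NA_real_))
      f1 <- ols_rss(cbind(X0, fv), d$y)
      lt <- lrt_gaussian(f0$rss, f1$rss, n, df = 1L)
      data.frame(factor = fn, n = n, stat = lt$stat, df = 1L, p = lt$p,
                 b_factor = f1$coef[4])
    }))
  })
  ids <- .eqtl_ids(names(by_eqtl)[keep])
  res <- cbind(ids[rep(seq_len(nrow(ids)), each = length(fnames)), ,
                   drop = FALSE],
               do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Test for higher-order (pseudotime x factor, GxExE) allelic effects
#'
#' Per eQTL and factor, tests the additional pseudotime-by-factor
#' interaction term on top of the cell-state model: 1-df likelihood ratio
#' test of `ASE ~ 1 + pseudo + pseudo^2 + factor + pseudo:factor` against
#' `ASE ~ 1 + pseudo + pseudo^2 + factor`.
#'
#' @inheritParams test_factor
#' @return data frame per (eQTL, factor) as in [test_factor()], with the
#'   interaction coefficient `b_inter`.
#' @export
test_higher_order <- function(records, pt, factors, min_cells = 50) {
  factors <- as.matrix(factors)
  by_eqtl <- .split_eqtl(records)
  keep <- vapply(by_eqtl, nrow, integer(1)) >= min_cells
  fnames <- colnames(factors)
  out <- lapply(by_eqtl[keep], function(r) {
    d <- .ase_design(r, pt, factors)
    n <- nrow(d)
    do.call(rbind, lapply(fnames, function(fn) {
      fv <- d[[fn]]
      if (sd(fv) == 0)
        return(data.frame(factor = fn, n = n, stat = NA_real_, df = 1L,
                          p = NA_real_, b_inter = NA_real_))
      X0 <- cbind(1, d$pseudo, d$pseudo2, fv)
      f0 <- ols_rss(X0, d$y)
      f1 <- ols_rss(cbind(X0, d$pseudo * fv), d$y)
      lt <- lrt_gaussian(f0$rss, f1$rss, n, df = 1L)
      data.frame(factor = fn, n = n, stat = lt$stat, df = 1L, p = lt$p,
                 b_inter = f1$coef[5])
    }))
  })
  ids <- .eqtl_ids(names(by_eqtl)[keep])
  res <- cbind(ids[rep(seq_len(nrow(ids)), each = length(fnames)), ,
                   drop = FALSE],
               do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjustment within one test family
#'
#' Families (dynamic, cell-state, higher-order) are corrected
#' independently and never pooled.
#'
#' @param results a result data frame from one family with a `p` column.
#' @return the data frame with an added `p_bh` column.
#' @export
bh_adjust <- function(results) {
  results$p_bh <- p.adjust(results$p, method = "BH")
  results
}

#' Classify eQTL by their interaction profile
#'
#' Combines the BH-adjusted dynamic and cell-state families into one of
#' four categories per eQTL: significant only with pseudotime
#' ("pseudotime"), only with at least one other cellular factor after
#' accounting for pseudotime ("factor"), with both ("both"), or neither
#' ("none").
#'
#' @param dynamic_res [test_dynamic()] results after [bh_adjust()].
#' @param factor_res [test_factor()] results after [bh_adjust()].
#' @param fdr significance threshold on adjusted p (default 0.10).
#' @return data frame: gene, variant, dynamic_sig, factor_sig, category.
#' @export
classify_eqtl <- function(dynamic_res, factor_res, fdr = 0.10) {
  key_d <- paste(dynamic_res$gene, dynamic_res$variant)
  dyn_sig <- setNames(dynamic_res$p_bh < fdr, key_d)
  key_f <- paste(factor_res$gene, factor_res$variant)
  fac_sig <- tapply(factor_res$p_bh < fdr, key_f,
                    function(x) any(x, na.rm = TRUE))
  keys <- union(key_d, names(fac_sig))
  ds <- ifelse(is.na(dyn_sig[keys]), FALSE, dyn_sig[keys])
  fs <- ifelse(is.na(fac_sig[keys]), FALSE, fac_sig[keys])
  category <- ifelse(ds & fs, "both",
                     ifelse(ds, "pseudotime",
                            ifelse(fs, "factor", "none")))
  parts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  data.frame(gene = parts[, 1], variant = parts[, 2],
             dynamic_sig = unname(ds), factor_sig = unname(fs),
             category = unname(category), stringsAsFactors = FALSE)
}

# Spectral clustering with a correlation-derived affinity. Rows of
# `profiles` are observations. Affinity (1 + r) / 2 keeps weights
# nonnegative; clustering uses the symmetric normalised Laplacian and a
# seeded k-means on the row-normalised eigenvector embedding.
spectral_cluster_profiles <- function(profiles, k, seed = 1L) {
  n <- nrow(profiles)
  if (k > n) stop("more clusters requested than profiles available")
  r <- suppressWarnings(cor(t(profiles)))
  r[is.na(r)] <- 0
  A <- (1 + r) / 2
  diag(A) <- 0
  dg <- pmax(rowSums(A), .Machine$double.eps)
  Dm <- 1 / sqrt(dg)
  L <- t(A * Dm) * Dm                      # D^-1/2 A D^-1/2
  eig <- eigen((L + t(L)) / 2, symmetric = TRUE)
  V <- eig$vectors[, seq_len(k), drop = FALSE]
  V <- V / pmax(sqrt(rowSums(V^2)), .Machine$double.eps)
  set.seed(seed)
  km <- kmeans(V, centers = k, nstart = 25, iter.max = 100)
  km$cluster
}

#' Jointly cluster expression and ASE dynamics along pseudotime
#'
#' Each eQTL contributes a pseudotime-window profile of mean expression and
#' one of mean ASE. Profiles are z-scored per row, stacked into one matrix
#' sharing the window axis, and grouped by spectral clustering with
#' `(1 + Pearson r) / 2` affinity, so the expression and ASE profiles of
#' the same gene may land in different clusters.
#'
#' @param expr_profiles eQTL x windows matrix of expression summaries.
#' @param ase_profiles eQTL x windows matrix of mean ASE (same row order).
#' @param k number of clusters (default 4).
#' @param seed seed for the k-means step.
#' @return list with `expression` and `ase` cluster label vectors (named by
#'   row), and `centers` (cluster x window matrix of mean z-scored
#'   profiles).
#' @export
cluster_dynamics <- function(expr_profiles, ase_profiles = NULL, k = 4,
                             seed = 1L) {
  ez <- zscore_rows(as.matrix(expr_profiles))
  stacked <- ez
  type <- rep("expression", nrow(ez))
  if (!is.null(ase_profiles)) {
    az <- zscore_rows(as.matrix(ase_profiles))
    stacked <- rbind(ez, az)
    type <- c(type, rep("ase", nrow(az)))
  }
  labels <- spectral_cluster_profiles(stacked, k = k, seed = seed)
  centers <- do.call(rbind, lapply(sort(unique(labels)), function(cl)
    colMeans(stacked[labels == cl, , drop = FALSE])))
  rownames(centers) <- paste0("cluster", sort(unique(labels)))
  out <- list(expression = setNames(labels[type == "expression"],
                                    rownames(expr_profiles)),
              centers = centers)
  if (!is.null(ase_profiles))
    out$ase <- setNames(labels[type == "ase"], rownames(ase_profiles))
  out
}
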