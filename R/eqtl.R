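#' Pseudo-bulk aggregation of single-cell expression
#'
#' Averages log2(CPM+1) over cells for each (donor, stratum, experiment)
#' combination, where the stratum is either the day of collection or the
#' assigned developmental stage. Donors run in several experiments keep one
#' row per experiment, retaining between-experiment differences that the
#' kinship random effect later absorbs.
#'
#' @param logcpm genes x cells log2(CPM+1) matrix.
#' @param meta per-cell metadata with donor, experiment, and the grouping
#'   column (`day` or `stage`; a `stage` column can be merged in from
#'   [assign_stages()]).
#' @param group_by `"day"` or `"stage"`.
#' @return object of class `aggregated_expression`: list with `values`
#'   (groups x genes matrix of mean log expression), and `groups` (data
#'   frame: donor, stratum, experiment, n_cells).
#' @export
aggregate_expression <- function(logcpm, meta, group_by = c("day", "stage")) {
  group_by <- match.arg(group_by)
  logcpm <- as.matrix(logcpm)
  m <- meta[match(colnames(logcpm), meta$cell), , drop = FALSE]
  if (is.null(m[[group_by]]))
    stop("metadata lacks a '", group_by, "' column")
  strat <- as.character(m[[group_by]])
  if (group_by == "stage") {
    keep <- strat != "unassigned"
  } else keep <- rep(TRUE, length(strat))
  key <- paste(m$donor, strat, m$experiment, sep = "\r")
  keys <- unique(key[keep])
  vals <- matrix(NA_real_, length(keys), nrow(logcpm),
                 dimnames = list(NULL, rownames(logcpm)))
  nc <- integer(length(keys))
  for (i in seq_along(keys)) {
    idx <- which(key == keys[i] & keep)
    vals[i, ] <- rowMeans(logcpm[, idx, drop = FALSE])
    nc[i] <- length(idx)
  }
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  groups <- data.frame(donor = parts[, 1], stratum = parts[, 2],
                       experiment = parts[, 3], n_cells = nc,
                       stringsAsFactors = FALSE)
  rownames(vals) <- paste(groups$donor, groups$stratum, groups$experiment,
                          sep = ".")
  structure(list(values = vals, groups = groups, group_by = group_by),
            class = "aggregated_expression")
}

#' Kinship matrix from genotype dosages
#'
#' Realised genetic relatedness `K = Z Z' / m` on dosages standardised per
#' variant to mean 0 and unit variance (population-style denominator, so a
#' single variant with dosages {0, 2} at frequency 0.5 yields unit
#' diagonal). Monomorphic variants are skipped.
#'
#' @param genotypes a `phased_genotypes` object (or a donors x variants
#'   dosage matrix).
#' @return object of class `kinship`: the donor x donor matrix with an
#'   `n_variants` attribute.
#' @export
estimate_kinship <- function(genotypes) {
  dos <- if (inherits(genotypes, "phased_genotypes"))
    genotype_dosage(genotypes) else as.matrix(genotypes)
  v <- apply(dos, 2L, function(x) mean((x - mean(x))^2))
  poly <- v > 0
  if (!any(poly)) stop("no polymorphic variants")
  Z <- scale(dos[, poly, drop = FALSE],
             center = TRUE, scale = sqrt(v[poly]))
  K <- tcrossprod(Z) / sum(poly)
  dimnames(K) <- list(rownames(dos), rownames(dos))
  structure(K, n_variants = sum(poly), class = c("kinship", "matrix", "array"))
}

#' Variance-component decomposition of single-cell expression
#'
#' Per gene, a random-effects model with experiment, day of collection and
#' cell-line intercepts (plus residual) is fitted by REML to the log
#' expression across cells, and each component is reported as a fraction of
#' the total variance.
#'
#' @param logcpm genes x cells matrix.
#' @param meta per-cell metadata with experiment, day, line columns.
#' @param genes optional subset of genes to decompose (default all).
#' @param n_cells number of randomly selected cells used (cost control).
#' @param seed seed for the cell subsample.
#' @return data frame per gene: fractions for experiment, day, line,
#'   residual (NA when the fit fails), and a `converged` flag.
#' @export
variance_components <- function(logcpm, meta, genes = NULL, n_cells = 5000,
                                seed = 1L) {
  logcpm <- as.matrix(logcpm)
  if (is.null(genes)) genes <- rownames(logcpm)
  m <- meta[match(colnames(logcpm), meta$cell), , drop = FALSE]
  for (col in c("experiment", "day", "line"))
    if (length(unique(m[[col]])) < 2L)
      stop("random effect '", col, "' needs at least 2 levels")
  set.seed(seed)
  idx <- if (ncol(logcpm) > n_cells)
    sort(sample(ncol(logcpm), n_cells)) else seq_len(ncol(logcpm))
  dat <- data.frame(experiment = m$experiment[idx], day = m$day[idx],
                    line = m$line[idx])
  out <- matrix(NA_real_, length(genes), 4L,
                dimnames = list(genes, c("experiment", "day", "line",
                                         "residual")))
  conv <- logical(length(genes))
  for (i in seq_along(genes)) {
    dat$y <- logcpm[genes[i], idx]
    fit <- tryCatch(
      lme4::lmer(y ~ (1 | experiment) + (1 | day) + (1 | line), data = dat,
                 REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    vc <- as.data.frame(lme4::VarCorr(fit))
    v <- setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual", vc$grp))
    tot <- sum(v)
    out[i, ] <- v[c("experiment", "day", "line", "residual")] / tot
    conv[i] <- TRUE
  }
  data.frame(gene = genes, out, converged = conv,
             stringsAsFactors = FALSE, row.names = NULL)
}

# ---- linear mixed model machinery (EMMA-style) ------------------------------

# ML log-likelihood of the null model (covariates only) at variance ratio
# delta = sigma_e^2 / sigma_g^2, after rotation by the eigenvectors of K.
.lmm_null_ll <- function(log_delta, S, yr, Wr) {
  delta <- exp(log_delta)
  w <- 1 / (S + delta)
  sw <- sqrt(w)
  fit <- stats::lm.fit(Wr * sw, yr * sw)
  rss <- sum(fit$residuals^2)
  n <- length(yr)
  -0.5 * (n * log(2 * pi * rss / n) + sum(log(S + delta)) + n)
}

# Fit the per-gene null variance ratio; returns list(delta, sw, Q, y_res,
# rss0) in the rotated, weighted coordinate system.
.lmm_null_fit <- function(S, yr, Wr) {
  opt <- optimize(function(ld) -.lmm_null_ll(ld, S, yr, Wr),
                  interval = c(-10, 10))
  delta <- exp(opt$minimum)
  sw <- sqrt(1 / (S + delta))
  Ww <- Wr * sw
  qrW <- qr(Ww)
  Q <- qr.Q(qrW)[, seq_len(qrW$rank), drop = FALSE]
  yw <- yr * sw
  y_res <- yw - Q %*% crossprod(Q, yw)
  list(delta = delta, sw = sw, Q = Q, y_res = as.numeric(y_res),
       rss0 = sum(y_res^2), rank_w = qrW$rank)
}

#' Map cis eQTL with a kinship-aware linear mixed model
#'
#' For each gene, variants with sample minor allele frequency above
#' `maf_min` within `window` bp of the gene body are tested in the model
#' `y = covariates c + x b + u + e`, `u ~ N(0, sg^2 K)`, with standardised
#' phenotype and dosage. The first `n_expr_pcs` expression principal
#' components (plus an intercept) are covariates. The variance ratio is
#' fitted once per gene under the null and reused across its variants; each
#' variant's significance is a 1-df likelihood ratio test. The lead variant
#' per gene has minimal p (ties broken by distance to the gene start, then
#' position).
#'
#' @param agg an [aggregate_expression()] result (one stratum at a time for
#'   stage-wise maps; rows of other strata can be filtered beforehand).
#' @param genotypes a `phased_genotypes` object covering the donors.
#' @param annot gene annotation data frame (gene, chrom, start, end).
#' @param kinship a [estimate_kinship()] matrix, or `NULL` for identity.
#' @param n_expr_pcs number of expression PCs used as covariates.
#' @param window cis window in bp either side of the gene body.
#' @param maf_min strict sample MAF threshold (computed on the unique
#'   donors present).
#' @param genes optional subset of genes to map.
#' @return object of class `eqtl_fit`: list with `results` (data frame:
#'   gene, variant, chrom, pos, beta, se, p, lead) and the per-gene fitting
#'   context consumed by [permutation_adjust()]. Genes with no testable
#'   variant are listed in `skipped`.
#' @export
map_cis_eqtl <- function(agg, genotypes, annot, kinship = NULL,
                         n_expr_pcs = 10, window = 250000, maf_min = 0.05,
                         genes = NULL) {
  stopifnot(inherits(agg, "aggregated_expression"))
  vals <- agg$values
  groups <- agg$groups
  n <- nrow(vals)
  if (n < 5L) stop("too few pseudo-bulk samples to map eQTL")
  donors_u <- unique(groups$donor)
  missing_d <- setdiff(donors_u, genotypes$donors)
  if (length(missing_d))
    stop("donors without genotypes: ", paste(missing_d, collapse = ", "))
  dos_u <- genotype_dosage(genotypes)[donors_u, , drop = FALSE]
  donor_idx <- match(groups$donor, donors_u)

  # sample-level kinship (identity when no kinship supplied)
  if (is.null(kinship)) {
    U <- diag(n); S <- rep(1, n)
  } else {
    Ks <- unclass(kinship)[groups$donor, groups$donor, drop = FALSE]
    eig <- eigen(Ks, symmetric = TRUE)
    U <- eig$vectors
    S <- pmax(eig$values, 0)
  }

  # covariates: intercept + expression PCs (genes standardised)
  X <- vals
  sds <- apply(X, 2L, sd)
  Xs <- scale(X[, sds > 0, drop = FALSE])
  # cap the covariate dimension so small strata keep residual degrees of
  # freedom for the per-variant test
  npc <- min(n_expr_pcs, floor(n / 4), ncol(Xs))
  W <- if (npc > 0) {
    cbind(1, prcomp(Xs, center = FALSE, rank. = npc)$x[, seq_len(npc),
                                                       drop = FALSE])
  } else matrix(1, n, 1L)
  Wr <- crossprod(U, W)

  # sample MAF over unique donors; variants need dosage variance (all-het
  # variants have MAF 0.5 but carry no dosage signal)
  f <- colMeans(dos_u) / 2
  maf <- pmin(f, 1 - f)
  dos_var <- apply(dos_u, 2L, var)
  v <- genotypes$variants

  if (is.null(genes)) genes <- intersect(annot$gene, colnames(vals))
  res <- vector("list", length(genes))
  ctx <- vector("list", length(genes))
  names(ctx) <- genes
  skipped <- character()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    a <- annot[annot$gene == g, , drop = FALSE]
    if (nrow(a) != 1L) { skipped <- c(skipped, g); next }
    inwin <- v$chrom == a$chrom & v$pos >= a$start - window &
      v$pos <= a$end + window & maf > maf_min & dos_var > 0
    if (!any(inwin)) { skipped <- c(skipped, g); next }
    vset <- v$id[inwin]
    y <- zscore(vals[, g])
    yr <- as.numeric(crossprod(U, y))
    nf <- .lmm_null_fit(S, yr, Wr)

    Gd <- dos_u[, vset, drop = FALSE]
    Xg <- scale(Gd[donor_idx, , drop = FALSE])   # samples x variants
    Xw <- crossprod(U, Xg) * nf$sw
    Xres <- Xw - nf$Q %*% crossprod(nf$Q, Xw)
    xx <- colSums(Xres^2)
    # variants collinear with the covariates carry no testable signal
    testable <- is.finite(xx) & xx > 1e-10
    if (!any(testable)) { skipped <- c(skipped, g); next }
    vset <- vset[testable]
    inwin <- which(inwin)[testable]
    Gd <- Gd[, testable, drop = FALSE]
    Xres <- Xres[, testable, drop = FALSE]
    xx <- xx[testable]
    xy <- colSums(Xres * nf$y_res)
    beta <- xy / xx
    rss1 <- pmax(nf$rss0 - xy^2 / xx, .Machine$double.eps)
    stat <- pmax(0, n * (log(nf$rss0) - log(rss1)))
    p <- pchisq(stat, df = 1L, lower.tail = FALSE)
    se <- sqrt(rss1 / (n - nf$rank_w - 1L) / xx)
    dist <- abs(v$pos[inwin] - a$start)
    ord <- order(p, dist, v$pos[inwin])
    lead <- seq_along(vset) == ord[1L]
    res[[gi]] <- data.frame(gene = g, variant = vset,
                            chrom = v$chrom[inwin], pos = v$pos[inwin],
                            beta = beta, se = se, p = p, lead = lead,
                            stringsAsFactors = FALSE)
    ctx[[g]] <- list(Gd = Gd, vset = vset, y_res = nf$y_res,
                     rss0 = nf$rss0, sw = nf$sw, Q = nf$Q,
                     obs_min_p = min(p))
  }
  results <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  rownames(results) <- NULL
  structure(list(results = results, skipped = skipped,
                 context = list(U = U, donor_idx = donor_idx, n = n,
                                n_donors = length(donors_u), genes = ctx)),
            class = "eqtl_fit")
}

#' @export
print.eqtl_fit <- function(x, ...) {
  cat(sprintf("cis-eQTL fit: %d genes, %d variant tests (%d genes skipped)\n",
              length(unique(x$results$gene)), nrow(x$results),
              length(x$skipped)))
  invisible(x)
}

#' Permutation-based gene-level adjusted p-values
#'
#' Donor labels of the genotypes are permuted `n_perm` times while
#' expression, covariates and kinship stay fixed; for each permutation the
#' minimum p over the gene's cis variants is recorded, and the adjusted p
#' is `(1 + #{perm min p <= observed min p}) / (n_perm + 1)`.
#'
#' @param fit an `eqtl_fit` from [map_cis_eqtl()].
#' @param n_perm number of permutations (default 1000).
#' @param seed seed for the permutation draws.
#' @return data frame: gene, p (observed minimum), p_adj.
#' @export
permutation_adjust <- function(fit, n_perm = 1000, seed = 1L) {
  stopifnot(inherits(fit, "eqtl_fit"))
  ctx <- fit$context
  set.seed(seed)
  perms <- t(replicate(n_perm, sample.int(ctx$n_donors)))
  genes <- names(ctx$genes)
  genes <- genes[!vapply(ctx$genes, is.null, logical(1))]
  n <- ctx$n
  Ut <- t(ctx$U)
  out <- data.frame(gene = genes, p = NA_real_, p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  # donor index of each sample under each permutation (n_perm x n samples)
  idx_mat <- matrix(perms[, ctx$donor_idx], nrow = n_perm)
  for (i in seq_along(genes)) {
    gc <- ctx$genes[[genes[i]]]
    k <- ncol(gc$Gd)
    # samples x (n_perm * k), permutation-major within each variant
    big <- gc$Gd[as.vector(t(idx_mat)), , drop = FALSE]
    dim(big) <- c(n, n_perm * k)
    Xw <- (Ut %*% big) * gc$sw
    Xres <- Xw - gc$Q %*% crossprod(gc$Q, Xw)
    xx <- colSums(Xres^2)
    xy <- colSums(Xres * gc$y_res)
    rss1 <- pmax(gc$rss0 - ifelse(xx > 0, xy^2 / xx, 0),
                 .Machine$double.eps)
    stat <- pmax(0, n * (log(gc$rss0) - log(rss1)))
    p <- pchisq(stat, df = 1L, lower.tail = FALSE)
    pm <- matrix(p, n_perm, k)
    min_p <- do.call(pmin, c(as.data.frame(pm), list(na.rm = TRUE)))
    out$p[i] <- gc$obs_min_p
    out$p_adj[i] <- (1 + sum(min_p <= gc$obs_min_p)) / (n_perm + 1)
  }
  out
}

#' Storey q-values with smoothed pi0 estimation
#'
#' Estimates the proportion of true nulls `pi0` on a lambda grid with a
#' cubic smoothing spline evaluated at the largest lambda, then computes
#' monotone q-values `q = pi0 * min_{j: p_j >= p} p_j m / rank_j`. With
#' `pi0 = 1` the procedure reduces exactly to Benjamini-Hochberg.
#'
#' @param p vector of (permutation-adjusted) p-values in [0, 1].
#' @param fdr significance threshold used for the `significant` flags.
#' @param lambda grid for pi0 estimation.
#' @param pi0 optional fixed pi0 (bypasses estimation).
#' @return list with `pi0`, `qvalue` (aligned with `p`), and `significant`
#'   (q < fdr).
#' @export
storey_fdr <- function(p, fdr = 0.10, lambda = seq(0.05, 0.95, 0.05),
                       pi0 = NULL) {
  if (!length(p)) stop("empty p-value vector")
  if (anyNA(p)) stop("p-values contain missing values")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pl <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    pi0 <- if (m < 50L || all(pl >= 1)) {
      1
    } else {
      sp <- smooth.spline(lambda, pl, df = 3)
      max(min(predict(sp, max(lambda))$y, 1), 1 / m)
    }
  }
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[ord] <- cummin(pi0 * p[ord] * m / rank(p, ties.method = "max")[ord])
  q <- pmin(q, 1)
  list(pi0 = pi0, qvalue = q, significant = q < fdr)
}

#' Cross-stratum sharing of lead eQTL effects
#'
#' A stratum-A lead effect is shared with stratum B when the same variant
#' is nominally significant in B (p < 0.05) with a consistent effect
#' direction; it is specific otherwise, and untestable when the variant was
#' not tested in B.
#'
#' @param lead_a data frame of stratum-A lead results (gene, variant,
#'   beta).
#' @param full_b data frame of all stratum-B results (gene, variant, beta,
#'   p).
#' @param alpha nominal replication threshold.
#' @return `lead_a` with added columns p_b, beta_b, status (shared /
#'   specific / untestable).
#' @export
replicate_and_share <- function(lead_a, full_b, alpha = 0.05) {
  key_a <- paste(lead_a$gene, lead_a$variant)
  key_b <- paste(full_b$gene, full_b$variant)
  j <- match(key_a, key_b)
  p_b <- full_b$p[j]
  beta_b <- full_b$beta[j]
  status <- ifelse(is.na(j), "untestable",
                   ifelse(p_b < alpha & sign(lead_a$beta) == sign(beta_b),
                          "shared", "specific"))
  cbind(lead_a, data.frame(p_b = p_b, beta_b = beta_b, status = status,
                           stringsAsFactors = FALSE))
}

#' Linkage disequilibrium between two variants
#'
#' Squared Pearson correlation of dosages across donors.
#'
#' @param genotypes a `phased_genotypes` object.
#' @param a,b variant ids.
#' @return r-squared in [0, 1].
#' @export
ld_r2 <- function(genotypes, a, b) {
  dos <- genotype_dosage(genotypes)
  for (id in c(a, b)) {
    if (!id %in% colnames(dos)) stop("unknown variant: ", id)
    if (var(dos[, id]) == 0) stop("monomorphic variant: ", id)
  }
  cor(dos[, a], dos[, b])^2
}

#' Detect lead-switching events across strata
#'
#' A switch event is a gene whose lead variants in two (or more) strata are
#' distinct, each significant at the given FDR, and pairwise not in LD
#' (r-squared below `r2_max`).
#'
#' @param results_by_stratum named list of per-stratum results, each with
#'   gene, variant, lead, and q columns (q from [storey_fdr()] applied to
#'   permutation-adjusted gene p merged back onto leads).
#' @param genotypes a `phased_genotypes` object.
#' @param r2_max LD threshold (default 0.2).
#' @param fdr significance threshold on q (default 0.10).
#' @return data frame of events: gene, strata, variants, max pairwise r2.
#' @export
detect_lead_switches <- function(results_by_stratum, genotypes,
                                 r2_max = 0.2, fdr = 0.10) {
  if (length(results_by_stratum) < 2L)
    stop("need at least two strata with results")
  leads <- do.call(rbind, lapply(names(results_by_stratum), function(s) {
    r <- results_by_stratum[[s]]
    r <- r[r$lead & !is.na(r$q) & r$q < fdr, c("gene", "variant"),
           drop = FALSE]
    if (nrow(r)) r$stratum <- s
    r
  }))
  out <- list()
  for (g in unique(leads$gene)) {
    sub <- leads[leads$gene == g, , drop = FALSE]
    vars <- unique(sub$variant)
    if (length(vars) < 2L) next
    pairs <- utils::combn(vars, 2L)
    r2 <- apply(pairs, 2L, function(pr) ld_r2(genotypes, pr[1], pr[2]))
    if (all(r2 < r2_max)) {
      out[[g]] <- data.frame(gene = g,
                             strata = paste(sub$stratum, collapse = ","),
                             variants = paste(vars, collapse = ","),
                             max_r2 = max(r2), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene = character(), strata = character(),
                      variants = character(), max_r2 = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
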