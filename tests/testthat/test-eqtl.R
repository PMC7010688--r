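test_that("pseudo-bulk aggregation averages cells per (donor, stratum, experiment)", {
  lc <- matrix(c(1, 3, 5, 7, 2, 4), nrow = 1,
               dimnames = list("gA", sprintf("c%d", 1:6)))
  meta <- data.frame(cell = sprintf("c%d", 1:6),
                     donor = c("d1", "d1", "d1", "d2", "d2", "d2"),
                     experiment = c("e1", "e1", "e2", "e1", "e1", "e1"),
                     day = "day0")
  agg <- aggregate_expression(lc, meta, "day")
  # two cells averaged; a donor in two experiments keeps two rows;
  # single-cell groups pass through
  expect_equal(nrow(agg$values), 3)
  d1e1 <- agg$groups$donor == "d1" & agg$groups$experiment == "e1"
  expect_equal(unname(agg$values[d1e1, "gA"]), 2)
  expect_equal(sum(agg$groups$donor == "d1"), 2)
  d1e2 <- agg$groups$donor == "d1" & agg$groups$experiment == "e2"
  expect_equal(unname(agg$values[d1e2, "gA"]), 5)
  expect_true(all(agg$groups$n_cells >= 1))
})

test_that("kinship equals standardised ZZ'/m and handles duplicates", {
  # hand-computed single variant, dosages {0, 2} at frequency 0.5
  g <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "v1"))
  K <- estimate_kinship(g)
  expect_equal(unclass(K), matrix(c(1, -1, -1, 1), 2,
                                  dimnames = list(c("a", "b"), c("a", "b"))),
               ignore_attr = TRUE)
  # duplicate donors: off-diagonal equals both diagonals
  set.seed(1)
  g2 <- matrix(rbinom(20, 2, 0.4), 4, 5,
               dimnames = list(c("a", "b", "c", "a2"), NULL))
  g2["a2", ] <- g2["a", ]
  K2 <- estimate_kinship(g2)
  expect_equal(K2["a", "a2"], K2["a", "a"])
  expect_equal(K2["a", "a2"], K2["a2", "a2"])
  # brute-force oracle on a random matrix
  set.seed(2)
  g3 <- matrix(rbinom(60, 2, 0.3), 6, 10,
               dimnames = list(sprintf("d%d", 1:6), NULL))
  poly <- apply(g3, 2, var) > 0
  Z <- apply(g3[, poly], 2, function(x)
    (x - mean(x)) / sqrt(mean((x - mean(x))^2)))
  expect_equal(unclass(estimate_kinship(g3)), Z %*% t(Z) / sum(poly),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(estimate_kinship(matrix(1, 3, 2)), "polymorphic")
})

test_that("variance components recover planted structure and sum to one", {
  set.seed(3)
  n <- 600
  meta <- data.frame(cell = sprintf("c%03d", 1:n),
                     experiment = sample(c("e1", "e2", "e3"), n, TRUE),
                     day = sample(paste0("day", 0:3), n, TRUE),
                     line = sample(sprintf("d%02d", 1:10), n, TRUE))
  line_eff <- rnorm(10, 0, 2)
  y_line <- line_eff[as.integer(factor(meta$line))] + rnorm(n, 0, 0.3)
  y_noise <- rnorm(n)
  x <- rbind(line_driven = y_line, pure_noise = y_noise)
  colnames(x) <- meta$cell
  vc <- variance_components(x, meta, n_cells = n, seed = 1)
  expect_gt(vc$line[1], 0.8)
  expect_gt(vc$residual[2], 0.9)
  sums <- rowSums(vc[, c("experiment", "day", "line", "residual")])
  expect_equal(sums, rep(1, 2), tolerance = 1e-6, ignore_attr = TRUE)
})

# shared LMM fixture: pseudo-bulk samples with known genotype effects
lmm_fixture <- function(seed = 1, n_donors = 30, n_genes = 50, beta = 0,
                        n_snps = 4, reps = 2, resid_sd = 1) {
  set.seed(seed)
  donors <- sprintf("d%02d", seq_len(n_donors))
  ids <- as.vector(outer(seq_len(n_snps), seq_len(n_genes),
                         function(s, g) sprintf("snp_g%03d_%d", g, s)))
  af <- runif(n_genes * n_snps, 0.2, 0.5)
  hap1 <- matrix(rbinom(n_donors * length(ids), 1, rep(af, each = n_donors)),
                 n_donors, dimnames = list(donors, ids))
  hap2 <- matrix(rbinom(n_donors * length(ids), 1, rep(af, each = n_donors)),
                 n_donors, dimnames = list(donors, ids))
  genes <- sprintf("g%03d", seq_len(n_genes))
  annot <- data.frame(gene = genes, chrom = "chr1",
                      start = seq_len(n_genes) * 1e7,
                      end = seq_len(n_genes) * 1e7 + 2e4)
  variants <- data.frame(id = ids, chrom = "chr1",
                         pos = rep(annot$start, each = n_snps) +
                           sample(-2e5:2e5, length(ids), TRUE),
                         ref = "A", alt = "G",
                         gene = rep(genes, each = n_snps), exonic = FALSE,
                         stringsAsFactors = FALSE)
  gt <- structure(list(hap1 = hap1, hap2 = hap2, variants = variants,
                       donors = donors), class = "phased_genotypes")
  groups <- data.frame(donor = rep(donors, reps), stratum = "day0",
                       experiment = rep(sprintf("e%d", seq_len(reps)),
                                        each = n_donors))
  dos <- hap1 + hap2
  causal <- sprintf("snp_g%03d_1", seq_len(n_genes))
  vals <- sapply(seq_len(n_genes), function(i) {
    x <- scale(dos[groups$donor, causal[i]])[, 1]
    if (is.na(x[1])) x <- rep(0, nrow(groups))
    beta * x + rnorm(nrow(groups), 0, resid_sd)
  })
  colnames(vals) <- genes
  rownames(vals) <- paste(groups$donor, groups$experiment)
  agg <- structure(list(values = vals, groups = groups, group_by = "day"),
                   class = "aggregated_expression")
  list(agg = agg, genotypes = gt, annot = annot, causal = causal)
}

test_that("a perfect genotype signal yields beta one and vanishing p", {
  fx <- lmm_fixture(seed = 4, n_donors = 20, n_genes = 3, reps = 1)
  dos <- genotype_dosage(fx$genotypes)
  vals <- fx$agg$values
  vals[, 1] <- scale(dos[fx$agg$groups$donor, fx$causal[1]])[, 1]
  agg <- fx$agg; agg$values <- vals
  fit <- map_cis_eqtl(agg, fx$genotypes, fx$annot, kinship = NULL,
                      n_expr_pcs = 0, genes = "g001")
  r <- fit$results[fit$results$variant == fx$causal[1], ]
  expect_equal(r$beta, 1, tolerance = 1e-6)
  expect_lt(r$p, 1e-10)
  expect_true(r$lead)
})

test_that("with identity kinship the LMM matches the OLS likelihood ratio test", {
  fx <- lmm_fixture(seed = 5, n_donors = 30, n_genes = 50, beta = 0.3)
  fit <- map_cis_eqtl(fx$agg, fx$genotypes, fx$annot, kinship = NULL,
                      n_expr_pcs = 5)
  # OLS oracle recomputed from scratch per gene/variant
  vals <- fx$agg$values
  Xs <- scale(vals[, apply(vals, 2, sd) > 0])
  W <- cbind(1, prcomp(Xs, center = FALSE, rank. = 5)$x[, 1:5])
  dos <- genotype_dosage(fx$genotypes)
  n <- nrow(vals)
  dmax <- 0
  for (i in sample(nrow(fit$results), 60)) {
    r <- fit$results[i, ]
    y <- scale(vals[, r$gene])[, 1]
    x <- scale(dos[fx$agg$groups$donor, r$variant])[, 1]
    rss0 <- sum(lm.fit(W, y)$residuals^2)
    rss1 <- sum(lm.fit(cbind(W, x), y)$residuals^2)
    p_ols <- pchisq(n * log(rss0 / rss1), 1, lower.tail = FALSE)
    dmax <- max(dmax, abs(p_ols - r$p))
  }
  expect_lt(dmax, 1e-8)
})

test_that("injected effects are recovered and the null is calibrated", {
  # effect of 0.5 sd on the standardised phenotype: residual sd
  # sqrt(1 - 0.25) keeps the phenotype at unit variance
  fx <- lmm_fixture(seed = 6, n_donors = 30, n_genes = 60, beta = 0.5,
                    reps = 3, resid_sd = sqrt(0.75))
  kin <- estimate_kinship(fx$genotypes)
  # no batch structure in the fixture: no PC covariates (at desk-scale
  # gene counts PCs partially absorb the per-gene cis signal)
  fit <- map_cis_eqtl(fx$agg, fx$genotypes, fx$annot, kinship = kin,
                      n_expr_pcs = 0)
  r <- fit$results
  causal_rows <- r[r$variant %in% fx$causal, ]
  ok <- abs(causal_rows$beta - 0.5) <= 0.15
  expect_gt(mean(ok), 0.8)
  # null phenotypes: nominal rejection near the asymptotic level
  fx0 <- lmm_fixture(seed = 7, n_donors = 30, n_genes = 150, beta = 0)
  fit0 <- map_cis_eqtl(fx0$agg, fx0$genotypes, fx0$annot, kinship = NULL,
                       n_expr_pcs = 5)
  rej <- mean(fit0$results$p < 0.05)
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("permutation adjustment follows the empirical-tail formula", {
  fx <- lmm_fixture(seed = 8, n_donors = 25, n_genes = 12, beta = 0.9)
  fit <- map_cis_eqtl(fx$agg, fx$genotypes, fx$annot, n_expr_pcs = 2)
  padj <- permutation_adjust(fit, n_perm = 1000, seed = 3)
  expect_true(all(padj$p_adj >= 1 / 1001))
  expect_true(all(padj$p_adj <= 1))
  # a strong signal beats every permutation: exact lower bound
  expect_true(any(padj$p_adj == 1 / 1001))
  # invariant to variant relabeling within a gene (same permutations)
  fit2 <- fit
  ctx <- fit2$context$genes[[1]]
  ord <- rev(seq_len(ncol(ctx$Gd)))
  fit2$context$genes[[1]]$Gd <- ctx$Gd[, ord, drop = FALSE]
  padj2 <- permutation_adjust(fit2, n_perm = 200, seed = 3)
  padj1 <- permutation_adjust(fit, n_perm = 200, seed = 3)
  expect_equal(padj1$p_adj, padj2$p_adj)
})

test_that("Storey q-values behave at the boundaries and reduce to BH", {
  # all p = 1
  st <- storey_fdr(rep(1, 20))
  expect_equal(st$pi0, 1)
  expect_true(all(st$qvalue == 1))
  # uniform p: pi0 near 1
  set.seed(9)
  p <- runif(1000)
  st2 <- storey_fdr(p)
  expect_lt(abs(st2$pi0 - 1), 0.1)
  # fixing pi0 = 1 reproduces BH exactly
  st3 <- storey_fdr(p, pi0 = 1)
  expect_equal(st3$qvalue, p.adjust(p, "BH"), tolerance = 1e-12)
  # q scales with pi0 relative to BH
  st4 <- storey_fdr(p, pi0 = 0.5)
  expect_equal(st4$qvalue, pmin(1, 0.5 * p.adjust(p, "BH")),
               tolerance = 1e-12)
  expect_true(all(diff(st2$qvalue[order(p)]) >= -1e-12))
  expect_error(storey_fdr(numeric()), "empty")
  expect_error(storey_fdr(c(0.5, 2)), "0, 1")
})

test_that("sharing status combines nominal significance and direction", {
  lead_a <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                       variant = c("v1", "v2", "v3", "v9"),
                       beta = c(1, 1, 1, 1))
  full_b <- data.frame(gene = c("g1", "g2", "g3"),
                       variant = c("v1", "v2", "v3"),
                       beta = c(0.5, 0.4, -0.5),
                       p = c(0.01, 0.2, 0.01))
  out <- replicate_and_share(lead_a, full_b)
  expect_identical(out$status,
                   c("shared", "specific", "specific", "untestable"))
})

test_that("LD r-squared is a squared correlation of dosages", {
  set.seed(10)
  hap1 <- matrix(rbinom(40, 1, 0.5), 10, 4)
  hap2 <- matrix(rbinom(40, 1, 0.5), 10, 4)
  gt <- tiny_genotypes(hap1, hap2)
  expect_equal(ld_r2(gt, "v1", "v1"), 1.0)
  # complementary dosages are perfectly correlated in r^2
  gt$hap1[, 2] <- 1 - gt$hap1[, 1]
  gt$hap2[, 2] <- 1 - gt$hap2[, 1]
  expect_equal(ld_r2(gt, "v1", "v2"), 1.0)
  # independent variants: E[r^2] ~ 1/(n-1)
  set.seed(11)
  n <- 40
  r2s <- replicate(300, {
    a <- rbinom(n, 2, 0.5); b <- rbinom(n, 2, 0.5)
    g <- tiny_genotypes(matrix(c(a > 0, b > 0), n), # dosage split irrelevant
                        matrix(c(pmax(a - 1, 0), pmax(b - 1, 0)), n))
    ld_r2(g, "v1", "v2")
  })
  expect_lt(abs(mean(r2s) - 1 / (n - 1)), 0.01)
  gt$hap1[, 3] <- 0; gt$hap2[, 3] <- 0
  expect_error(ld_r2(gt, "v1", "v3"), "monomorphic")
})

test_that("lead switches require distinct significant leads not in LD", {
  set.seed(12)
  hap1 <- matrix(rbinom(200, 1, 0.5), 50, 4)
  hap2 <- matrix(rbinom(200, 1, 0.5), 50, 4)
  gt <- tiny_genotypes(hap1, hap2)
  gt$hap1[, 2] <- gt$hap1[, 1]; gt$hap2[, 2] <- gt$hap2[, 1] # v2 = v1 (LD 1)
  mk <- function(variant, q) data.frame(gene = "geneA", variant = variant,
                                        lead = TRUE, q = q,
                                        stringsAsFactors = FALSE)
  # same lead twice: no event
  ev <- detect_lead_switches(list(a = mk("v1", 0.01), b = mk("v1", 0.01)),
                             gt)
  expect_equal(nrow(ev), 0)
  # distinct leads in strong LD: no event
  ev2 <- detect_lead_switches(list(a = mk("v1", 0.01), b = mk("v2", 0.01)),
                              gt)
  expect_equal(nrow(ev2), 0)
  # distinct independent leads, both significant: event
  ev3 <- detect_lead_switches(list(a = mk("v1", 0.01), b = mk("v3", 0.01)),
                              gt)
  expect_equal(ev3$gene, "geneA")
  # not significant in one stratum: no event
  ev4 <- detect_lead_switches(list(a = mk("v1", 0.01), b = mk("v3", 0.5)),
                              gt)
  expect_equal(nrow(ev4), 0)
})
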