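mk_eff_fixture <- function(seed = 1, n_donors = 50, n_expt = 3,
                           marker_effect = 0, noise = 0.05) {
  set.seed(seed)
  donors <- sprintf("d%02d", seq_len(n_donors))
  marker <- rnorm(n_donors)
  recs <- do.call(rbind, lapply(seq_len(n_expt), function(e)
    data.frame(donor = donors, experiment = sprintf("e%d", e),
               efficiency = 0.5 + marker_effect * marker +
                 rnorm(1, 0, 0.02) + rnorm(n_donors, 0, noise),
               n_cells = 20L, stringsAsFactors = FALSE)))
  list(records = recs, marker = data.frame(donor = donors, m = marker),
       marker_values = marker)
}

test_that("efficiency is the mean day-3 pseudotime per (donor, experiment)", {
  cells <- sprintf("c%02d", 1:40)
  pt <- data.frame(cell = cells,
                   pseudotime = c(rep(0.85, 12), rep(0.75, 9),
                                  rep(0.9, 12), rep(0.2, 7)))
  meta <- data.frame(cell = cells,
                     donor = c(rep("d1", 12), rep("d2", 9),
                               rep("d1", 12), rep("d3", 7)),
                     experiment = c(rep("e1", 12), rep("e1", 9),
                                    rep("e2", 12), rep("e1", 7)),
                     day = c(rep("day3", 33), rep("day0", 7)))
  eff <- differentiation_efficiency(pt, meta, min_cells = 10)
  # d2 has only 9 day-3 cells: excluded; d3 has no day-3 cells
  expect_equal(nrow(eff), 2)
  expect_setequal(eff$donor, "d1")
  # a donor in two experiments yields two records
  expect_setequal(eff$experiment, c("e1", "e2"))
  expect_equal(eff$efficiency[eff$experiment == "e1"], 0.85)
  expect_equal(eff$efficiency[eff$experiment == "e2"], 0.9)
  expect_error(differentiation_efficiency(pt, meta, min_cells = 50),
               "reaches")
})

test_that("constant markers give a null likelihood ratio", {
  fx <- mk_eff_fixture(seed = 2)
  mk <- data.frame(donor = fx$marker$donor, m = 1)
  res <- test_marker_lmm(fx$records, mk)
  expect_equal(res$stat, 0)
  expect_equal(res$p, 1)
})

test_that("marker effects are detected with high power and calibrated under permutation", {
  det <- vapply(1:40, function(i) {
    fx <- mk_eff_fixture(seed = 100 + i, marker_effect = 0.5 * 0.1,
                         noise = 0.05)
    test_marker_lmm(fx$records, fx$marker)$p
  }, numeric(1))
  expect_gt(mean(det < 0.01), 0.9)
  # permuted markers: uniform p
  set.seed(4)
  pv <- vapply(1:100, function(i) {
    fx <- mk_eff_fixture(seed = 200 + i, marker_effect = 0)
    test_marker_lmm(fx$records, fx$marker)$p
  }, numeric(1))
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("the mixed model agrees with ordinary regression when variances vanish", {
  # independent observations, one per (donor, experiment) cell of a grid
  checked <- 0
  for (i in 1:20) {
    fx <- mk_eff_fixture(seed = 300 + i, marker_effect = 0, noise = 0.1)
    # remove the experiment shifts so both random variances can hit zero
    fx$records$efficiency <- 0.5 + rnorm(nrow(fx$records), 0, 0.1)
    res <- test_marker_lmm(fx$records, fx$marker)
    # only compare replicates where the ML fit put BOTH variances at zero
    dat0 <- merge(fx$records, fx$marker, by = "donor")
    names(dat0)[names(dat0) == "m"] <- "marker"
    refit <- lme4::lmer(efficiency ~ marker + (1 | experiment) +
                          (1 | donor), data = dat0, REML = FALSE,
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(refit))
    if (any(vc$vcov[vc$grp != "Residual"] > 1e-10)) next
    dat <- merge(fx$records, fx$marker, by = "donor")
    f0 <- lm(efficiency ~ 1, dat)
    f1 <- lm(efficiency ~ m, dat)
    stat <- nrow(dat) * log(sum(resid(f0)^2) / sum(resid(f1)^2))
    p_ols <- pchisq(stat, 1, lower.tail = FALSE)
    expect_equal(res$p, p_ols, tolerance = 1e-6)
    checked <- checked + 1
    if (checked >= 3) break
  }
  expect_gte(checked, 1)
})

test_that("replication requires nominal significance and a consistent direction", {
  set.seed(5)
  donors <- sprintf("d%02d", 1:40)
  marker <- rnorm(40)
  resp <- data.frame(donor = donors, value = 0.3 * marker + rnorm(40, 0, 0.1))
  mk <- data.frame(donor = donors, value = marker)
  rep1 <- replicate_marker(resp, mk, discovery_effect = 1)
  expect_true(rep1$replicated)
  expect_identical(rep1$direction, "consistent")
  # sign flip in the replication data breaks the direction
  resp2 <- resp; resp2$value <- -resp2$value
  rep2 <- replicate_marker(resp2, mk, discovery_effect = 1)
  expect_false(rep2$replicated)
  expect_identical(rep2$direction, "inconsistent")
  # uncorrelated replication marker is not significant (typically)
  mk3 <- data.frame(donor = donors, value = rnorm(40))
  pv <- replicate(100, {
    r <- data.frame(donor = donors, value = rnorm(40))
    replicate_marker(r, mk, discovery_effect = NA)$p
  })
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
  expect_error(replicate_marker(resp[1:2, ], mk), "overlapping")
})

test_that("sex effects are detected and symmetric under relabeling", {
  fx <- mk_eff_fixture(seed = 6, noise = 0.05)
  sex <- data.frame(donor = fx$marker$donor,
                    sex = rep(c("female", "male"), length.out = 50))
  shifted <- fx$records
  male <- sex$donor[sex$sex == "male"]
  shifted$efficiency <- shifted$efficiency +
    0.2 * (shifted$donor %in% male)
  res <- test_sex_effect(shifted, sex)
  expect_lt(res$p, 0.01)
  # relabeling flips the sign but not the p-value
  sex2 <- sex
  sex2$sex <- ifelse(sex$sex == "male", "aaa_male", "zzz_female")
  res2 <- test_sex_effect(shifted, sex2)
  expect_equal(res2$p, res$p, tolerance = 1e-6)
  expect_equal(res2$effect, -res$effect, tolerance = 1e-6)
  expect_error(test_sex_effect(shifted, within(sex, sex <- "female")),
               "both sexes")
})

test_that("chromosome enrichment reproduces the fold-change construction", {
  universe <- sprintf("g%03d", 1:100)
  gene_chrom <- setNames(c(rep("chrX", 10), rep("chr1", 90)), universe)
  hits <- c(universe[1:5], universe[11:15])      # 5 of 10 on chrX
  enr <- chromosome_enrichment(hits, gene_chrom, universe)
  expect_equal(enr$fold, (5 / 10) / (10 / 100))  # = 5
  expect_lt(enr$p, 0.01)
  # hits distributed like the universe: fold ~ 1, p large
  enr2 <- chromosome_enrichment(c(universe[1], universe[11:19]),
                                gene_chrom, universe)
  expect_equal(enr2$fold, 1)
  expect_gt(enr2$p, 0.3)
  expect_error(chromosome_enrichment(character(), gene_chrom, universe),
               "empty")
})

test_that("simulated line-specific differentiation rates are rank-recovered", {
  cfg <- simulation_config(seed = 31)      # default design
  gt <- simulate_genotypes(cfg)
  sim <- simulate_cells(cfg, gt)
  ds <- list(counts = sim$counts, meta = sim$meta, truth = sim$truth)
  lc <- normalize_log_cpm(ds$counts)
  hvg <- highly_variable_genes(lc, ds$meta)
  pt <- compute_pseudotime(lc, hvg$gene, ds$meta, n_genes = 100)
  eff <- differentiation_efficiency(pt, ds$meta, min_cells = 10)
  per_donor <- tapply(eff$efficiency, eff$donor, mean)
  truth <- ds$truth$donors
  rho <- cor(per_donor,
             truth$differentiation_rate[match(names(per_donor),
                                              truth$donor)],
             method = "spearman")
  expect_gt(rho, 0.9)
})
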