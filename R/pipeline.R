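#' Pipeline configuration
#'
#' Bundles the simulation conditions, QC thresholds, and all analysis
#' parameters with their standard defaults: 250 kb cis window, MAF > 5%,
#' 1000 permutations, 10 expression PCs, pseudotime from the top HVGs,
#' sliding windows of 25% of cells stepping by 2.5%, at least 50 ASE cells
#' per interaction test, FDR 10%, and at least 10 day-3 cells per
#' efficiency record. QC thresholds default to values sized for the
#' synthetic desk-scale data (full-scale defaults live in
#' [qc_thresholds()]).
#'
#' @param sim a [simulation_config()].
#' @param qc a [qc_thresholds()].
#' @param n_hvg_pseudotime HVGs used for pseudotime.
#' @param cis_window cis window in bp.
#' @param maf_min MAF threshold.
#' @param n_perm genotype permutations per gene.
#' @param n_expr_pcs expression PCs as eQTL covariates.
#' @param window_frac,window_step sliding-window sizing.
#' @param min_ase_cells minimum ASE records per interaction test.
#' @param fdr FDR threshold used throughout.
#' @param min_efficiency_cells minimum day-3 cells per efficiency record.
#' @param n_top_expressed genes entering co-expression clustering.
#' @param n_factor_modules number of (largest) modules used as cellular
#'   factors.
#' @param n_clusters clusters for the dynamics profiles.
#' @param vc_genes,vc_cells scope of the variance-component decomposition.
#' @param seed master seed.
#' @return object of class `pipeline_config` (a list).
#' @export
pipeline_config <- function(sim = simulation_config(),
                            qc = qc_thresholds(min_endogenous_counts = 2000,
                                               min_genes_detected = 100,
                                               max_top100_fraction = 1,
                                               max_mt_fraction = 0.15,
                                               min_mapping_rate = 0.60),
                            n_hvg_pseudotime = 100,
                            cis_window = 250000,
                            maf_min = 0.05,
                            n_perm = 1000,
                            n_expr_pcs = 10,
                            window_frac = 0.25,
                            window_step = 0.025,
                            min_ase_cells = 50,
                            fdr = 0.10,
                            min_efficiency_cells = 10,
                            n_top_expressed = 8000,
                            n_factor_modules = 2,
                            n_clusters = 4,
                            vc_genes = 50,
                            vc_cells = 2000,
                            seed = 1L) {
  structure(list(sim = sim, qc = qc,
                 n_hvg_pseudotime = n_hvg_pseudotime,
                 cis_window = cis_window, maf_min = maf_min,
                 n_perm = n_perm, n_expr_pcs = n_expr_pcs,
                 window_frac = window_frac, window_step = window_step,
                 min_ase_cells = min_ase_cells, fdr = fdr,
                 min_efficiency_cells = min_efficiency_cells,
                 n_top_expressed = n_top_expressed,
                 n_factor_modules = n_factor_modules,
                 n_clusters = n_clusters, vc_genes = vc_genes,
                 vc_cells = vc_cells, seed = as.integer(seed)),
            class = "pipeline_config")
}

.pipeline_stages <- c("simulate", "preprocess", "trajectory", "eqtl",
                      "ase", "modules", "interactions", "efficiency")

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Executes simulate, preprocess, trajectory, eqtl, ase, modules,
#' interactions and efficiency in dependency order. Later stages require
#' their upstream stages (e.g. `ase` needs `eqtl` leads); requesting a
#' stage without its dependencies is an error. All randomness derives from
#' the config seed, so a re-run reproduces every output exactly.
#'
#' @param config a [pipeline_config()].
#' @param stages stages to run (default all, in order).
#' @param out_dir optional directory; when given, the main result tables
#'   are written as TSVs with provenance headers.
#' @return named list with the outputs of every executed stage.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = .pipeline_stages, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  deps <- list(preprocess = "simulate", trajectory = "preprocess",
               eqtl = "trajectory", ase = "eqtl", modules = "preprocess",
               interactions = c("ase", "modules"),
               efficiency = c("trajectory", "eqtl"))
  for (s in stages) {
    miss <- setdiff(deps[[s]], stages)
    if (length(miss))
      stop("stage '", s, "' requires stage(s): ",
           paste(miss, collapse = ", "))
  }
  res <- list(config = config)
  run <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if ("simulate" %in% stages) {
    res$dataset <- run("simulate", simulate_dataset(config$sim))
  }
  if ("preprocess" %in% stages) {
    res$preprocess <- run("preprocess", {
      ds <- res$dataset
      mt_genes <- ds$annotation$gene[ds$annotation$mt]
      kept <- qc_filter_cells(ds$counts, ds$meta, config$qc, mt_genes)
      counts_qc <- ds$counts[, kept, drop = FALSE]
      logcpm_all <- normalize_log_cpm(counts_qc)
      expressed <- filter_expressed_genes(ds$counts, logcpm_all, ds$meta)
      logcpm <- logcpm_all[expressed, , drop = FALSE]
      hvg <- highly_variable_genes(logcpm, ds$meta, fdr = 0.01)
      list(kept_cells = kept, expressed_genes = expressed,
           logcpm = logcpm, hvg = hvg,
           log = c(cells_in = ncol(ds$counts), cells_kept = length(kept),
                   genes_in = nrow(ds$counts),
                   genes_expressed = length(expressed)))
    })
  }
  if ("trajectory" %in% stages) {
    res$trajectory <- run("trajectory", {
      pp <- res$preprocess
      meta <- res$dataset$meta
      pt <- compute_pseudotime(pp$logcpm, pp$hvg$gene, meta,
                               n_genes = config$n_hvg_pseudotime)
      stage <- assign_stages(pt, meta)
      windows <- sliding_windows(pt, config$window_frac,
                                 config$window_step)
      list(pt = pt, stage = stage, windows = windows)
    })
  }
  if ("eqtl" %in% stages) {
    res$eqtl <- run("eqtl", {
      ds <- res$dataset
      pp <- res$preprocess
      tj <- res$trajectory
      meta <- ds$meta
      meta$stage <- tj$stage$stage[match(meta$cell, tj$stage$cell)]
      kin <- estimate_kinship(ds$genotypes)
      agg_all <- aggregate_expression(pp$logcpm, meta, "stage")
      per_stage <- list()
      for (s in intersect(c("iPSC", "mesendo", "defendo"),
                          unique(agg_all$groups$stratum))) {
        rows <- agg_all$groups$stratum == s
        agg_s <- structure(list(values = agg_all$values[rows, ,
                                                        drop = FALSE],
                                groups = agg_all$groups[rows, ,
                                                        drop = FALSE],
                                group_by = "stage"),
                           class = "aggregated_expression")
        fit <- map_cis_eqtl(agg_s, ds$genotypes, ds$annotation,
                            kinship = kin, n_expr_pcs = config$n_expr_pcs,
                            window = config$cis_window,
                            maf_min = config$maf_min)
        padj <- permutation_adjust(fit, n_perm = config$n_perm,
                                   seed = config$seed)
        st <- storey_fdr(padj$p_adj, fdr = config$fdr)
        padj$q <- st$qvalue
        r <- fit$results
        j <- match(r$gene, padj$gene)
        r$p_adj <- padj$p_adj[j]
        r$q <- padj$q[j]
        per_stage[[s]] <- list(results = r, gene_level = padj,
                               pi0 = st$pi0,
                               egenes = padj$gene[st$significant])
      }
      vc <- variance_components(pp$logcpm, meta,
                                genes = head(rownames(pp$logcpm),
                                             config$vc_genes),
                                n_cells = config$vc_cells,
                                seed = config$seed)
      switches <- if (length(per_stage) >= 2L)
        detect_lead_switches(lapply(per_stage, `[[`, "results"),
                             ds$genotypes, fdr = config$fdr)
      else NULL
      list(kinship = kin, per_stage = per_stage,
           variance_components = vc, lead_switches = switches)
    })
  }
  if ("ase" %in% stages) {
    res$ase <- run("ase", {
      ds <- res$dataset
      tj <- res$trajectory
      # one eQTL variant per gene: the lead from its most significant stage
      leads <- do.call(rbind, lapply(names(res$eqtl$per_stage), function(s) {
        r <- res$eqtl$per_stage[[s]]$results
        r <- r[r$lead, , drop = FALSE]
        r$stage <- s
        r
      }))
      leads <- leads[order(leads$gene, leads$q, leads$p), , drop = FALSE]
      leads <- leads[!duplicated(leads$gene), , drop = FALSE]
      cd <- setNames(ds$meta$donor, ds$meta$cell)
      rec <- ase_gene_records(ds$allelic_counts, ds$genotypes, cd,
                              leads[, c("gene", "variant")])
      rec <- rec[rec$cell %in% res$preprocess$kept_cells, , drop = FALSE]
      binned <- bin_ase_pseudotime(rec, tj$windows)
      list(leads = leads, records = rec, binned = binned)
    })
  }
  if ("modules" %in% stages) {
    res$modules <- run("modules", {
      pp <- res$preprocess
      top <- suppressWarnings(
        select_top_expressed(pp$logcpm, config$n_top_expressed))
      mods <- affinity_propagation_modules(pp$logcpm[top, , drop = FALSE],
                                           seed = config$seed)
      sizes <- table(mods$modules$module)
      fac_ids <- names(sort(sizes, decreasing = TRUE))[
        seq_len(min(config$n_factor_modules, length(sizes)))]
      scores <- module_scores(pp$logcpm, mods, fac_ids)
      list(modules = mods, factor_modules = fac_ids, scores = scores)
    })
  }
  if ("interactions" %in% stages) {
    res$interactions <- run("interactions", {
      rec <- res$ase$records
      pt <- res$trajectory$pt
      fac <- res$modules$scores
      dyn <- bh_adjust(test_dynamic(rec, pt, config$min_ase_cells))
      gxe <- bh_adjust(test_factor(rec, pt, fac, config$min_ase_cells))
      gxexe <- bh_adjust(test_higher_order(rec, pt, fac,
                                           config$min_ase_cells))
      cls <- classify_eqtl(dyn, gxe, fdr = config$fdr)
      # window profiles for the tested eQTL: expression + ASE dynamics
      tested <- unique(dyn[, c("gene", "variant")])
      binned <- res$ase$binned
      prof <- NULL
      if (nrow(tested) >= config$n_clusters) {
        wins <- res$trajectory$windows$windows$window
        ase_m <- matrix(NA_real_, nrow(tested), length(wins),
                        dimnames = list(paste(tested$gene, tested$variant),
                                        wins))
        for (i in seq_len(nrow(tested))) {
          b <- binned[binned$gene == tested$gene[i] &
                      binned$variant == tested$variant[i], , drop = FALSE]
          ase_m[i, match(b$window, wins)] <- b$mean_ase
        }
        ok <- rowSums(is.na(ase_m)) == 0
        expr_m <- t(vapply(which(ok), function(i) {
          vapply(res$trajectory$windows$members, function(cells)
            mean(res$preprocess$logcpm[tested$gene[i],
                 intersect(cells, colnames(res$preprocess$logcpm))]),
            numeric(1))
        }, numeric(length(wins))))
        rownames(expr_m) <- rownames(ase_m)[ok]
        prof <- if (sum(ok) >= config$n_clusters)
          cluster_dynamics(expr_m, ase_m[ok, , drop = FALSE],
                           k = config$n_clusters, seed = config$seed)
        else NULL
      }
      list(dynamic = dyn, factor = gxe, higher_order = gxexe,
           classification = cls, dynamics_clusters = prof)
    })
  }
  if ("efficiency" %in% stages) {
    res$efficiency <- run("efficiency", {
      ds <- res$dataset
      effr <- differentiation_efficiency(res$trajectory$pt, ds$meta,
                                         config$min_efficiency_cells)
      # genetic markers: dosages of the per-gene lead eQTL variants
      leads <- res$ase$leads
      dos <- genotype_dosage(ds$genotypes)
      gm <- data.frame(donor = ds$genotypes$donors,
                       dos[, unique(leads$variant), drop = FALSE],
                       check.names = FALSE, stringsAsFactors = FALSE)
      genetic <- test_marker_lmm(effr, gm, kind = "genetic",
                                 fdr = config$fdr)
      # expression markers: iPSC-stage pseudo-bulk expression per
      # (donor, experiment)
      meta <- ds$meta
      meta$stage <- res$trajectory$stage$stage[match(meta$cell,
                                                     res$trajectory$stage$cell)]
      agg <- aggregate_expression(res$preprocess$logcpm, meta, "stage")
      rows <- agg$groups$stratum == "iPSC"
      em <- data.frame(donor = agg$groups$donor[rows],
                       experiment = agg$groups$experiment[rows],
                       agg$values[rows, , drop = FALSE],
                       check.names = FALSE, stringsAsFactors = FALSE)
      expression <- test_marker_lmm(effr, em, kind = "expression",
                                    fdr = config$fdr)
      sex_res <- if (!is.null(ds$meta$sex))
        test_sex_effect(effr, unique(ds$meta[, c("donor", "sex")]))
      else NULL
      list(records = effr, genetic = genetic, expression = expression,
           sex = sex_res)
    })
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    sd <- config$seed
    if (!is.null(res$trajectory))
      write_tsv_provenance(res$trajectory$stage,
                           file.path(out_dir, "pseudotime_stages.tsv"), sd)
    if (!is.null(res$eqtl))
      for (s in names(res$eqtl$per_stage))
        write_tsv_provenance(res$eqtl$per_stage[[s]]$results,
                             file.path(out_dir,
                                       paste0("eqtl_", s, ".tsv")), sd)
    if (!is.null(res$ase))
      write_tsv_provenance(res$ase$binned,
                           file.path(out_dir, "ase_binned.tsv"), sd)
    if (!is.null(res$interactions))
      write_tsv_provenance(res$interactions$dynamic,
                           file.path(out_dir, "ase_dynamic_tests.tsv"), sd)
    if (!is.null(res$efficiency))
      write_tsv_provenance(res$efficiency$genetic,
                           file.path(out_dir, "efficiency_markers.tsv"), sd)
  }
  res
}
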