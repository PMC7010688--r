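#' Differentiation efficiency per (donor, experiment)
#'
#' The efficiency of a cell line in an experiment is the mean pseudotime of
#' its day-3 cells; groups with fewer than `min_cells` contributing cells
#' are excluded. Donors differentiated in several experiments yield one
#' record per experiment.
#'
#' @param pt pseudotime data frame ([compute_pseudotime()]).
#' @param meta per-cell metadata with donor, experiment, day.
#' @param min_cells minimum day-3 cells per group (default 10).
#' @param day label of the terminal day (default "day3").
#' @return data frame: donor, experiment, efficiency, n_cells.
#' @export
differentiation_efficiency <- function(pt, meta, min_cells = 10,
                                       day = "day3") {
  m <- meta[match(pt$cell, meta$cell), , drop = FALSE]
  sel <- m$day == day
  if (!any(sel)) stop("no cells collected at ", day)
  key <- paste(m$donor[sel], m$experiment[sel], sep = "\r")
  agg <- tapply(pt$pseudotime[sel], key, mean)
  n <- tapply(pt$pseudotime[sel], key, length)
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  out <- data.frame(donor = parts[, 1], experiment = parts[, 2],
                    efficiency = as.numeric(agg), n_cells = as.integer(n),
                    stringsAsFactors = FALSE)
  out <- out[out$n_cells >= min_cells, , drop = FALSE]
  if (!nrow(out)) stop("no (donor, experiment) group reaches ", min_cells,
                       " cells at ", day)
  rownames(out) <- NULL
  out
}

# Mixed model LRT of a fixed marker effect with experiment and donor
# random intercepts, ML-fitted for a valid likelihood ratio.
.efficiency_lrt <- function(dat) {
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  full <- lme4::lmer(efficiency ~ marker + (1 | experiment) + (1 | donor),
                     data = dat, REML = FALSE, control = ctrl)
  null <- lme4::lmer(efficiency ~ 1 + (1 | experiment) + (1 | donor),
                     data = dat, REML = FALSE, control = ctrl)
  stat <- max(0, as.numeric(2 * (stats::logLik(full) - stats::logLik(null))))
  list(stat = stat, p = pchisq(stat, df = 1L, lower.tail = FALSE),
       effect = lme4::fixef(full)[["marker"]],
       singular = lme4::isSingular(full))
}

#' Mixed-model association of markers with differentiation efficiency
#'
#' Per marker, fits `efficiency = marker + (1 | experiment) + (1 | donor)`
#' and tests the fixed marker effect by a 1-df likelihood ratio against the
#' model without the marker; BH adjustment across markers. Genetic markers
#' are allele dosages (0/1/2) of lead eQTL variants; expression markers are
#' per-(donor, experiment) iPSC-stage expression levels.
#'
#' @param records efficiency records from [differentiation_efficiency()].
#' @param markers a data frame of marker values: either per donor (columns
#'   `donor`, one column per marker) or per (donor, experiment) (columns
#'   `donor`, `experiment`, one per marker).
#' @param kind label stored with the results ("genetic", "expression", ...).
#' @param fdr BH threshold for the `significant` flags.
#' @return data frame per marker: marker, kind, effect, stat, p, p_bh,
#'   significant, singular flag, n records used.
#' @export
test_marker_lmm <- function(records, markers, kind = "marker", fdr = 0.10) {
  if (length(unique(records$experiment)) < 2L ||
      length(unique(records$donor)) < 2L)
    stop("need at least 2 experiments and 2 donors")
  by_expt <- "experiment" %in% names(markers)
  idcols <- if (by_expt) c("donor", "experiment") else "donor"
  mcols <- setdiff(names(markers), idcols)
  out <- lapply(mcols, function(mc) {
    j <- if (by_expt)
      match(paste(records$donor, records$experiment),
            paste(markers$donor, markers$experiment))
    else match(records$donor, markers$donor)
    dat <- data.frame(efficiency = records$efficiency,
                      experiment = records$experiment,
                      donor = records$donor, marker = markers[[mc]][j])
    dat <- dat[complete.cases(dat), , drop = FALSE]
    if (length(unique(dat$marker)) < 2L)
      return(data.frame(marker = mc, kind = kind, effect = NA_real_,
                        stat = 0, p = 1, singular = NA, n = nrow(dat),
                        stringsAsFactors = FALSE))
    fit <- tryCatch(.efficiency_lrt(dat), error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(marker = mc, kind = kind, effect = NA_real_,
                        stat = NA_real_, p = NA_real_, singular = TRUE,
                        n = nrow(dat), stringsAsFactors = FALSE))
    data.frame(marker = mc, kind = kind, effect = fit$effect,
               stat = fit$stat, p = fit$p, singular = fit$singular,
               n = nrow(dat), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$p_bh <- p.adjust(res$p, "BH")
  res$significant <- !is.na(res$p_bh) & res$p_bh < fdr
  rownames(res) <- NULL
  res
}

#' Replicate a marker association in independent measurements
#'
#' Simple linear regression of an independent response (e.g. bulk-derived
#' differentiation efficiency or a FACS positivity fraction) on the marker
#' across overlapping donors. Replication requires nominal p < 0.05 and a
#' direction consistent with the discovery effect.
#'
#' @param response data frame with donor and value columns (independent
#'   measurement per donor).
#' @param marker data frame with donor and value columns.
#' @param discovery_effect signed discovery effect estimate (for direction
#'   consistency), or NA to skip the direction check.
#' @param alpha nominal replication threshold.
#' @return list: n, slope, p, direction ("consistent"/"inconsistent"/NA),
#'   replicated.
#' @export
replicate_marker <- function(response, marker, discovery_effect = NA,
                             alpha = 0.05) {
  j <- match(response$donor, marker$donor)
  dat <- data.frame(y = response$value, x = marker$value[j])
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 3L) stop("fewer than 3 overlapping donors")
  fit <- summary(lm(y ~ x, data = dat))
  slope <- fit$coefficients["x", "Estimate"]
  p <- fit$coefficients["x", "Pr(>|t|)"]
  direction <- if (is.na(discovery_effect)) NA_character_ else
    if (sign(slope) == sign(discovery_effect)) "consistent" else
      "inconsistent"
  replicated <- p < alpha &&
    (is.na(discovery_effect) || identical(direction, "consistent"))
  list(n = nrow(dat), slope = slope, p = p, direction = direction,
       replicated = replicated)
}

#' Sex effect on differentiation efficiency
#'
#' Fits the same mixed model as [test_marker_lmm()] with donor sex as the
#' fixed effect.
#'
#' @param records efficiency records.
#' @param sex data frame with donor and sex columns (two levels).
#' @return one-row data frame: effect (second level vs first), stat, p,
#'   singular, n.
#' @export
test_sex_effect <- function(records, sex) {
  s <- factor(sex$sex[match(records$donor, sex$donor)])
  if (nlevels(droplevels(s)) < 2L) stop("both sexes must be present")
  dat <- data.frame(efficiency = records$efficiency,
                    experiment = records$experiment, donor = records$donor,
                    marker = as.numeric(s == levels(s)[2L]))
  dat <- dat[complete.cases(dat), , drop = FALSE]
  fit <- .efficiency_lrt(dat)
  data.frame(marker = "sex", kind = "sex", effect = fit$effect,
             stat = fit$stat, p = fit$p, singular = fit$singular,
             n = nrow(dat), stringsAsFactors = FALSE)
}

#' Chromosome enrichment among significant markers
#'
#' Fisher's exact test of membership on a chromosome among significant
#' markers versus the tested universe, with fold enrichment
#' `(hits_on_chrom / hits) / (universe_on_chrom / universe)`.
#'
#' @param hits character vector of significant marker genes.
#' @param gene_chrom named character vector mapping gene to chromosome.
#' @param universe character vector of all tested genes.
#' @param chrom chromosome of interest (default "chrX").
#' @return list: fold, p, hits_on_chrom, universe_on_chrom.
#' @export
chromosome_enrichment <- function(hits, gene_chrom, universe,
                                  chrom = "chrX") {
  if (!length(hits)) stop("empty hit set")
  hits <- intersect(hits, universe)
  on_c <- names(gene_chrom)[gene_chrom == chrom]
  a <- length(intersect(hits, on_c))
  b <- length(hits) - a
  cc <- length(intersect(setdiff(universe, hits), on_c))
  d <- length(universe) - length(hits) - cc
  fold <- (a / length(hits)) /
    ((a + cc) / length(universe))
  p <- fisher.test(matrix(c(a, b, cc, d), 2L),
                   alternative = "greater")$p.value
  list(fold = fold, p = p, hits_on_chrom = a, universe_on_chrom = a + cc)
}
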