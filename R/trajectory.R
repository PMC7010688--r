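#' Differentiation pseudotime from the first principal component
#'
#' Pseudotime is the first principal component of cells over the top
#' highly variable genes (genes centred and scaled to unit variance),
#' oriented so that it correlates positively with the day of collection
#' (Spearman), then linearly rescaled so the observed minimum is 0 and the
#' maximum is 1.
#'
#' @param logcpm genes x cells log2(CPM+1) matrix.
#' @param hvg_genes character vector of highly variable genes ranked by
#'   decreasing biological variance (e.g. `highly_variable_genes()$gene`).
#' @param meta per-cell metadata with a `day` column (labels day0..day3).
#' @param n_genes number of top HVGs to use (default 500; capped at the
#'   number available).
#' @return data frame: cell, pc1 (raw score), pseudotime in [0, 1],
#'   orientation (+1/-1 sign applied to PC1).
#' @export
compute_pseudotime <- function(logcpm, hvg_genes, meta, n_genes = 500) {
  logcpm <- as.matrix(logcpm)
  if (ncol(logcpm) < 3L) stop("need at least 3 cells")
  use <- head(intersect(hvg_genes, rownames(logcpm)), n_genes)
  if (!length(use)) stop("no highly variable genes present in the matrix")
  x <- t(logcpm[use, , drop = FALSE])         # cells x genes
  sds <- apply(x, 2L, sd)
  if (all(sds == 0)) stop("degenerate expression matrix: all genes constant")
  x <- scale(x[, sds > 0, drop = FALSE])
  pc1 <- prcomp(x, center = FALSE, scale. = FALSE, rank. = 1L)$x[, 1L]
  day_num <- day_to_numeric(meta$day[match(colnames(logcpm), meta$cell)])
  orientation <- 1
  rho <- suppressWarnings(cor(pc1, day_num, method = "spearman"))
  if (is.finite(rho) && rho < 0) orientation <- -1
  score <- orientation * pc1
  rng <- range(score)
  if (rng[1] == rng[2]) stop("degenerate PC1: zero variance across cells")
  data.frame(cell = colnames(logcpm), pc1 = pc1,
             pseudotime = (score - rng[1]) / (rng[2] - rng[1]),
             orientation = orientation,
             stringsAsFactors = FALSE, row.names = colnames(logcpm))
}

#' Assign cells to developmental stages
#'
#' Stage labels combine the collection day with pseudotime windows around
#' the expression peaks of canonical markers: mesendoderm for day1/day2
#' cells with pseudotime in [0.15, 0.5]; definitive endoderm for day2/day3
#' cells with pseudotime above 0.7; all day0 cells are iPSC; anything else
#' (notably intermediate pseudotime between 0.5 and 0.7) is unassigned.
#'
#' @param pt data frame from [compute_pseudotime()].
#' @param meta per-cell metadata with a `day` column.
#' @return data frame: cell, day, pseudotime, stage (one of iPSC, mesendo,
#'   defendo, unassigned).
#' @export
assign_stages <- function(pt, meta) {
  day <- as.character(meta$day[match(pt$cell, meta$cell)])
  day_to_numeric(day)  # validates the labels
  p <- pt$pseudotime
  stage <- rep("unassigned", nrow(pt))
  stage[day %in% c("day1", "day2") & p >= 0.15 & p <= 0.5] <- "mesendo"
  stage[day %in% c("day2", "day3") & p > 0.7] <- "defendo"
  stage[day == "day0"] <- "iPSC"
  data.frame(cell = pt$cell, day = day, pseudotime = p, stage = stage,
             stringsAsFactors = FALSE, row.names = pt$cell)
}

#' Sliding pseudotime windows
#'
#' Cells are ranked by pseudotime (ties broken by cell id for
#' reproducibility) and grouped into overlapping windows each holding
#' `round(frac * N)` cells, with consecutive window starts
#' `round(step * N)` ranks apart; windows are emitted while they fit
#' entirely within the N cells.
#'
#' @param pt data frame from [compute_pseudotime()] (or any data frame with
#'   `cell` and `pseudotime` columns).
#' @param frac fraction of cells per window (default 0.25).
#' @param step fraction of cells between window starts (default 0.025).
#' @return object of class `window_set`: list with `windows` (data frame:
#'   window id, start rank, end rank, center = mean pseudotime, n) and
#'   `members` (named list of cell-id vectors).
#' @export
sliding_windows <- function(pt, frac = 0.25, step = 0.025) {
  if (!(step > 0 && step <= frac && frac < 1))
    stop("require 0 < step <= frac < 1")
  n <- nrow(pt)
  w <- round(frac * n)
  s <- round(step * n)
  if (w < 1L || s < 1L || w > n)
    stop("too few cells for one window at frac=", frac)
  ord <- order(pt$pseudotime, pt$cell)
  cells <- pt$cell[ord]
  ptime <- pt$pseudotime[ord]
  starts <- seq(0L, n - w, by = s)
  ids <- sprintf("window%03d", seq_along(starts))
  members <- lapply(starts, function(st) cells[(st + 1L):(st + w)])
  names(members) <- ids
  centers <- vapply(starts, function(st) mean(ptime[(st + 1L):(st + w)]),
                    numeric(1))
  windows <- data.frame(window = ids, start_rank = starts + 1L,
                        end_rank = starts + w, center = centers, n = w,
                        stringsAsFactors = FALSE)
  structure(list(windows = windows, members = members, frac = frac,
                 step = step), class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("Sliding windows: %d windows of %d cells (frac=%.3f, step=%.3f)\n",
              nrow(x$windows), x$windows$n[1], x$frac, x$step))
  invisible(x)
}
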