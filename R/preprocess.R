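#' Filter barcodes by complexity and housekeeping expression
#'
#' A barcode is retained when (1) its complexity — the number of distinct
#' genes detected — is at least `complexity_cutoff` and (2) its mean
#' `log2(1 + TP10k)` over a curated housekeeping gene list is at least
#' `hk_cutoff`. The defaults (400 genes, 1.6) are the CSF settings; PBL data
#' use a 200-gene complexity cutoff.
#'
#' @param counts A `count_matrix`.
#' @param housekeeping Character vector of housekeeping gene symbols; genes
#'   missing from the matrix are ignored with a warning.
#' @param complexity_cutoff Minimum number of detected genes (default 400).
#' @param hk_cutoff Minimum mean log2(1 + TP10k) over housekeeping genes
#'   (default 1.6).
#' @return List with `counts` (retained cells) and `qc` (a per-cell
#'   `data.frame` of complexity, housekeeping score and pass flags, plus
#'   attributes `n_retained` / `n_removed`).
#' @export
filter_barcodes <- function(counts, housekeeping,
                            complexity_cutoff = 400L, hk_cutoff = 1.6) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  hk <- intersect(housekeeping, counts$genes)
  if (length(hk) < length(housekeeping))
    warning(sprintf("%d housekeeping genes absent from matrix; ignored",
                    length(housekeeping) - length(hk)), call. = FALSE)
  if (!length(hk))
    stop("no housekeeping genes present in matrix", call. = FALSE)
  complexity <- Matrix::colSums(m > 0)
  totals <- Matrix::colSums(m)
  tp10k_hk <- t(t(as.matrix(m[hk, , drop = FALSE])) /
                  pmax(totals, 1)) * 1e4
  hk_score <- colMeans(log2(1 + tp10k_hk))
  pass_complexity <- complexity >= complexity_cutoff
  pass_hk <- hk_score >= hk_cutoff
  keep <- pass_complexity & pass_hk
  qc <- data.frame(barcode = counts$cells,
                   complexity = as.integer(complexity),
                   hk_score = hk_score,
                   pass_complexity = pass_complexity,
                   pass_hk = pass_hk,
                   retained = keep,
                   row.names = NULL)
  attr(qc, "n_retained") <- sum(keep)
  attr(qc, "n_removed") <- sum(!keep)
  if (!any(keep))
    warning("no barcodes pass QC", call. = FALSE)
  out <- count_matrix(m[, keep, drop = FALSE])
  list(counts = out, qc = qc)
}

#' Retain genes detected in a minimum fraction of cells
#'
#' Keeps genes with a nonzero count in at least `min_fraction` of the cells.
#' The threshold is the exact product `min_fraction * n_cells` compared with
#' `>=`; it is never rounded down, so with any positive fraction a gene must
#' be detected in at least one cell. The pipeline applies 1% for general
#' analysis and 0.0875% for the windowed-expression input, always after
#' barcode filtering ("remaining barcodes").
#'
#' @param counts A `count_matrix`.
#' @param min_fraction Detection fraction in `[0, 1]`.
#' @return Filtered `count_matrix`.
#' @export
filter_genes <- function(counts, min_fraction) {
  stopifnot(inherits(counts, "count_matrix"),
            min_fraction >= 0, min_fraction <= 1)
  if (min_fraction == 0) return(counts)
  detected <- Matrix::rowSums(counts$counts > 0)
  keep <- detected / length(counts$cells) >= min_fraction
  count_matrix(counts$counts[keep, , drop = FALSE])
}

#' TP10k and log2 normalization
#'
#' Scales each cell to 10,000 UMIs (TP10k) and takes `log2(1 + TP10k)`.
#'
#' @param counts A `count_matrix` with no all-zero cells.
#' @return List of class `normalized_matrix` with `genes`, `cells`, dense
#'   matrices `tp10k` and `log2_tp10k`, and `layer = "log2_tp10k"`.
#' @export
normalize_tp10k_log <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  totals <- Matrix::colSums(counts$counts)
  if (any(totals == 0))
    stop("value error: all-zero cell(s): ",
         paste(utils::head(counts$cells[totals == 0], 5), collapse = ", "),
         call. = FALSE)
  tp10k <- as.matrix(counts$counts) %*% Matrix::Diagonal(x = 1e4 / totals)
  tp10k <- as.matrix(tp10k)
  dimnames(tp10k) <- list(counts$genes, counts$cells)
  structure(list(genes = counts$genes, cells = counts$cells,
                 tp10k = tp10k, log2_tp10k = log2(1 + tp10k),
                 layer = "log2_tp10k"),
            class = "normalized_matrix")
}

#' Downsample each cell to a fixed UMI total
#'
#' Cells whose total exceeds `target` have exactly `target` UMIs drawn
#' without replacement from their observed UMI pool (a multivariate
#' hypergeometric draw), so expected gene proportions are preserved and no
#' count ever increases. Cells at or below `target` are left unchanged and
#' flagged. Used to equalize cell quality before CSF-vs-PBL comparison
#' (target 500, the approximate mean UMI count of PBL cells).
#'
#' @param counts A `count_matrix`.
#' @param target Total UMIs per cell after downsampling (default 500).
#' @param seed Optional seed making the draw reproducible.
#' @return A `count_matrix`; attribute `below_target` names the unchanged
#'   cells.
#' @export
downsample_cell_umis <- function(counts, target = 500L, seed = NULL) {
  stopifnot(inherits(counts, "count_matrix"), target > 0)
  run <- function() {
    m <- as.matrix(counts$counts)
    totals <- colSums(m)
    for (i in which(totals > target)) {
      pool <- rep.int(seq_len(nrow(m)), m[, i])
      drawn <- pool[sample.int(length(pool), target)]
      m[, i] <- tabulate(drawn, nbins = nrow(m))
    }
    out <- count_matrix(m, counts$genes, counts$cells)
    attr(out, "below_target") <- counts$cells[totals <= target & totals > 0]
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
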