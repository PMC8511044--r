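#' Remove the overlap between two gene signatures
#'
#' Genes shared by the named pair (e.g. the IFN-gamma response and antigen
#' presentation signatures, which overlap substantially) are removed from
#' both sets before scoring, so each score reflects its own program. Other
#' sets are untouched.
#'
#' @param sets A `gene_set_collection`.
#' @param pair Character vector of two set names.
#' @return The collection with the pair de-overlapped. Fully overlapping
#'   sets become empty with a warning (and are dropped).
#' @export
sanitize_gene_sets <- function(sets, pair) {
  stopifnot(length(pair) == 2)
  miss <- setdiff(pair, names(sets))
  if (length(miss))
    stop("gene set(s) not found: ", paste(miss, collapse = ", "), call. = FALSE)
  ov <- intersect(sets[[pair[1]]], sets[[pair[2]]])
  out <- unclass(sets)
  out[[pair[1]]] <- setdiff(out[[pair[1]]], ov)
  out[[pair[2]]] <- setdiff(out[[pair[2]]], ov)
  emptied <- pair[lengths(out[pair]) == 0]
  if (length(emptied)) {
    warning("set(s) emptied by overlap removal: ",
            paste(emptied, collapse = ", "), call. = FALSE)
    out <- out[lengths(out) > 0]
  }
  gene_set_collection(out)
}

#' Bin-matched background-subtracted module score
#'
#' Per-cell score of a gene set: the mean log-normalized expression of the
#' set genes minus the mean expression of a pool of control genes. Controls
#' are drawn, for each set gene, from the expression bin (of `n_bins` bins
#' of average expression across the scored cells) containing that gene,
#' excluding set genes, so the background matches the set's expression
#' profile and the expected score of a random set is zero. When scoring a
#' subset of cells, bins and averages are recomputed over that subset.
#'
#' @param expr A `normalized_matrix`.
#' @param gene_set Character vector of set genes; genes missing from the
#'   matrix are dropped with a warning.
#' @param cell_subset Optional barcodes to score (default: all cells).
#' @param n_bins Number of average-expression bins (default 25).
#' @param n_ctrl Control genes sampled per set gene (default 100); bins
#'   smaller than `n_ctrl` are sampled exhaustively with a warning.
#' @param seed Seed for control sampling (default 1).
#' @return `data.frame` with columns `barcode`, `score`; attributes
#'   `controls` (sampled control genes), `bins` (per-gene bin assignment),
#'   `seed`, `dropped` (set genes absent from the matrix).
#' @export
module_score <- function(expr, gene_set, cell_subset = NULL,
                         n_bins = 25L, n_ctrl = 100L, seed = 1L) {
  cells <- if (is.null(cell_subset)) expr$cells else cell_subset
  stopifnot(all(cells %in% expr$cells))
  m <- expr$log2_tp10k[, cells, drop = FALSE]
  dropped <- setdiff(gene_set, expr$genes)
  if (length(dropped))
    warning(sprintf("%d set genes absent from matrix; dropped", length(dropped)),
            call. = FALSE)
  gene_set <- intersect(gene_set, expr$genes)
  if (!length(gene_set))
    stop("empty gene set after filtering to the matrix", call. = FALSE)
  avg <- rowMeans(m)
  # equal-occupancy bins of average expression over the scored subset
  rk <- rank(avg, ties.method = "first")
  bins <- as.integer(cut(rk, breaks = n_bins, labels = FALSE))
  names(bins) <- expr$genes
  n_short <- 0L
  controls <- withr::with_seed(seed, {
    unlist(lapply(gene_set, function(g) {
      pool <- expr$genes[bins == bins[[g]]]
      pool <- setdiff(pool, gene_set)
      if (!length(pool)) return(character())
      if (length(pool) < n_ctrl) {
        n_short <<- n_short + 1L
        pool
      } else sample(pool, n_ctrl)
    }), use.names = FALSE)
  })
  if (n_short > 0)
    warning(sprintf("%d of %d set genes sit in bins with fewer than %d control candidates; their bins were used exhaustively",
                    n_short, length(gene_set), n_ctrl), call. = FALSE)
  if (!length(controls))
    stop("no control genes available", call. = FALSE)
  score <- colMeans(m[gene_set, , drop = FALSE]) -
    colMeans(m[controls, , drop = FALSE])
  out <- data.frame(barcode = cells, score = unname(score), row.names = NULL)
  attr(out, "controls") <- controls
  attr(out, "bins") <- bins
  attr(out, "seed") <- seed
  attr(out, "dropped") <- dropped
  out
}
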