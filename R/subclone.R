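#' Kendall tau rank correlation (tie-corrected)
#'
#' Tau-b between two numeric vectors, computed with an O(n log n) merge-sort
#' kernel. Returns `NA` when either vector is constant.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Tau-b in `[-1, 1]`, or `NA`.
#' @export
kendall_tau <- function(x, y) .tau_b(as.numeric(x), as.numeric(y))

#' Pairwise 1 - tau distance matrix between cells
#'
#' The cell-cell distance used for subclone discovery: `1 - tau_K`, where
#' `tau_K` is the tie-corrected Kendall correlation between the WME profiles
#' (not their ranks) of each pair of cells. Distances lie in `[0, 2]`.
#' A cell with a constant profile has undefined tau; its distances are set
#' to 1 by convention, with a warning.
#'
#' @param wme Matrix windows x cells (the WME layer).
#' @param cells Optional cell names (defaults to `colnames(wme)`).
#' @return Symmetric distance matrix with zero diagonal, of class
#'   `distance_matrix`.
#' @export
kendall_distance_matrix <- function(wme, cells = colnames(wme)) {
  if (ncol(wme) < 2) stop("need >= 2 cells", call. = FALSE)
  tau <- .tau_b_matrix(as.matrix(wme))
  if (anyNA(tau)) {
    warning("constant cell profile(s): tau undefined, distance set to 1",
            call. = FALSE)
    tau[is.na(tau)] <- 0
  }
  d <- 1 - tau
  diag(d) <- 0
  dimnames(d) <- list(cells, cells)
  class(d) <- c("distance_matrix", class(d))
  d
}

#' Weighted-linkage (WPGMA) agglomerative clustering of cells
#'
#' Agglomerates the 1 - tau distance matrix with weighted linkage and cuts
#' the dendrogram to exactly `k` clusters. Singleton clusters — single
#' outlier cells — are flagged and excluded from clone-role assignment.
#'
#' @param dist A `distance_matrix` (or symmetric matrix).
#' @param k Number of clusters to cut (default 4).
#' @return List of class `subclone_assignment`: `cells`, `cluster` (integer
#'   label per cell), `sizes`, `is_singleton` (per cluster), `clone_role`
#'   (per cluster, filled by [label_clones()]), and `hclust` (the
#'   dendrogram).
#' @export
cluster_wpgma <- function(dist, k = 4L) {
  n <- nrow(dist)
  if (k < 2) stop("value error: k must be >= 2", call. = FALSE)
  if (k > n) stop("value error: k exceeds number of cells", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(dist), method = "mcquitty")
  cl <- stats::cutree(hc, k = k)
  sizes <- tabulate(cl, nbins = k)
  structure(list(cells = rownames(dist), cluster = unname(cl), sizes = sizes,
                 is_singleton = sizes == 1L,
                 clone_role = rep(NA_character_, k),
                 hclust = hc),
            class = "subclone_assignment")
}

#' @export
print.subclone_assignment <- function(x, ...) {
  cat(sprintf("<subclone_assignment> %d cells in %d clusters (sizes: %s)\n",
              length(x$cells), length(x$sizes),
              paste(x$sizes, collapse = ", ")))
  roles <- x$clone_role[!x$is_singleton]
  if (any(!is.na(roles)))
    cat("  roles:", paste(stats::na.omit(roles), collapse = ", "), "\n")
  invisible(x)
}

#' PCA + UMAP embedding of rWME profiles
#'
#' Principal components of the rank-transformed WME, followed by a 2-D UMAP
#' of the first `n_pcs` components. Visualization only: cluster labels are
#' never derived from the embedding. Falls back to the first two principal
#' components when the `uwot` package is unavailable.
#'
#' @param rwme Matrix windows x cells of rWME values.
#' @param n_pcs Number of principal components (default 50; truncated with a
#'   warning when it exceeds the data rank).
#' @param seed Seed for the stochastic embedding.
#' @return List with `pca` (cells x n_pcs scores), `layout` (cells x 2) and
#'   `method` ("umap" or "pca").
#' @export
embed_rwme <- function(rwme, n_pcs = 50L, seed = 1L) {
  if (ncol(rwme) < 3) stop("value error: need >= 3 cells to embed", call. = FALSE)
  max_pc <- min(nrow(rwme), ncol(rwme) - 1L)
  if (n_pcs > max_pc) {
    warning(sprintf("n_pcs truncated from %d to %d", n_pcs, max_pc), call. = FALSE)
    n_pcs <- max_pc
  }
  pc <- stats::prcomp(t(rwme), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  if (requireNamespace("uwot", quietly = TRUE)) {
    layout <- withr::with_seed(seed, uwot::umap(
      scores, n_neighbors = min(15, ncol(rwme) - 1), n_threads = 1))
    method <- "umap"
  } else {
    layout <- scores[, 1:2, drop = FALSE]
    method <- "pca"
  }
  rownames(layout) <- colnames(rwme)
  list(pca = scores, layout = layout, method = method)
}

#' Per-sample fractional abundance of each subclone
#'
#' Among malignant cells of each sample, the fraction belonging to each
#' cluster. Singleton clusters are reported separately and fractions sum to
#' 1 over all reported clusters per sample. Samples with no malignant cells
#' are omitted with a warning.
#'
#' @param assignment A `subclone_assignment`.
#' @param metadata A `cell_metadata` covering the assigned cells.
#' @return `data.frame` with columns `sample_id`, `days_since_first_dose`,
#'   `cluster`, `n_cells`, `fraction`, `is_singleton`.
#' @export
clone_fractions <- function(assignment, metadata) {
  md <- metadata[match(assignment$cells, metadata$barcode), ]
  if (anyNA(md$barcode))
    stop("assigned cells missing from metadata", call. = FALSE)
  empty <- setdiff(unique(metadata$sample_id[metadata$is_malignant]),
                   unique(md$sample_id))
  if (length(empty))
    warning("sample(s) without malignant cells omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
  out <- list()
  for (s in unique(md$sample_id)) {
    in_s <- md$sample_id == s
    n <- sum(in_s)
    tab <- table(factor(assignment$cluster[in_s],
                        levels = seq_along(assignment$sizes)))
    out[[s]] <- data.frame(sample_id = s,
                           days_since_first_dose = md$days_since_first_dose[in_s][1],
                           cluster = as.integer(names(tab)),
                           n_cells = as.integer(tab),
                           fraction = as.numeric(tab) / n,
                           is_singleton = assignment$is_singleton,
                           row.names = NULL)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$days_since_first_dose, out$sample_id, out$cluster), ]
}

#' Label subclones as ascendant or descendant from their trajectories
#'
#' Expects exactly two non-singleton clusters. The cluster whose
#' malignant-cell fraction increases from the first to the last time point
#' is labeled `ascendant`, the other `descendant`. Ties, a single time
#' point, or more than two major clusters leave the roles `unassigned` with
#' a warning.
#'
#' @param assignment A `subclone_assignment`.
#' @param metadata A `cell_metadata`.
#' @return The assignment with `clone_role` filled per cluster and a
#'   `fractions` element attached.
#' @export
label_clones <- function(assignment, metadata) {
  fr <- clone_fractions(assignment, metadata)
  assignment$fractions <- fr
  major <- which(!assignment$is_singleton)
  assignment$clone_role[] <- NA_character_
  assignment$clone_role[major] <- "unassigned"
  days <- sort(unique(fr$days_since_first_dose))
  if (length(days) < 2) {
    warning("single time point: clone roles unassigned", call. = FALSE)
    return(assignment)
  }
  if (length(major) != 2) {
    warning(sprintf("%d non-singleton clusters (expected 2): roles unassigned",
                    length(major)), call. = FALSE)
    return(assignment)
  }
  delta <- vapply(major, function(cl) {
    first <- fr$fraction[fr$cluster == cl & fr$days_since_first_dose == days[1]]
    last <- fr$fraction[fr$cluster == cl & fr$days_since_first_dose == days[length(days)]]
    mean(last) - mean(first)
  }, numeric(1))
  if (any(delta == 0) || all(delta > 0) || all(delta < 0)) {
    warning("tied or non-opposing trajectories: roles unassigned", call. = FALSE)
    return(assignment)
  }
  assignment$clone_role[major[which.max(delta)]] <- "ascendant"
  assignment$clone_role[major[which.min(delta)]] <- "descendant"
  assignment
}

#' Write the clustering dendrogram in Newick format
#'
#' @param assignment A `subclone_assignment` (carries the hclust tree).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(assignment, path) {
  ape::write.tree(ape::as.phylo(assignment$hclust), file = path)
  invisible(path)
}
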