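#' Select genes eligible for CNV window construction
#'
#' Removes genes in the uppermost decile of dropout rate (fraction of cells
#' with zero count, computed over all retained cells) and all
#' immunoglobulin-flagged genes, whose expression reflects B-cell state
#' rather than copy number.
#'
#' @param counts A `count_matrix` of retained cells.
#' @param annotation A `gene_annotation`.
#' @param dropout_quantile Quantile of the per-gene dropout distribution at
#'   and above which genes are excluded (default 0.9).
#' @return Character vector of eligible gene symbols, in genomic order
#'   (chromosome, then order_index).
#' @export
select_cnv_genes <- function(counts, annotation, dropout_quantile = 0.9) {
  stopifnot(inherits(counts, "count_matrix"))
  ann <- annotation[match(counts$genes, annotation$symbol), ]
  present <- !is.na(ann$symbol)
  dropout <- 1 - Matrix::rowSums(counts$counts > 0) / length(counts$cells)
  cut <- stats::quantile(dropout, dropout_quantile, names = FALSE)
  keep <- present & dropout < cut & !ann$is_immunoglobulin
  eligible <- counts$genes[keep]
  if (!length(eligible)) {
    warning("no genes eligible for CNV windows", call. = FALSE)
    return(character())
  }
  ann <- annotation[match(eligible, annotation$symbol), ]
  chr_rank <- match(ann$chromosome, unique(annotation$chromosome))
  eligible[order(chr_rank, ann$order_index)]
}

#' Build fixed-length gene windows along the genome
#'
#' Tiles each chromosome with windows of `window_size` genes consecutive in
#' the post-exclusion genomic ordering, advancing by `stride` genes (the
#' default stride 1 gives all possible windows). Every gene in a window lies
#' on one chromosome; chromosomes with fewer eligible genes than
#' `window_size` contribute no windows.
#'
#' @param annotation A `gene_annotation`.
#' @param eligible Character vector of eligible gene symbols (see
#'   [select_cnv_genes()]).
#' @param window_size Genes per window (default 200).
#' @param stride Genes between window starts (default 1).
#' @return A list of class `window_set`: `windows` (list of
#'   `list(chromosome, genes, index)`), `window_size`, `stride`.
#' @export
build_windows <- function(annotation, eligible, window_size = 200L, stride = 1L) {
  if (window_size <= 0) stop("value error: window_size must be positive", call. = FALSE)
  if (stride <= 0) stop("value error: stride must be positive", call. = FALSE)
  ann <- annotation[match(eligible, annotation$symbol), ]
  if (anyNA(ann$symbol))
    stop("eligible genes missing from annotation", call. = FALSE)
  ord <- order(match(ann$chromosome, unique(annotation$chromosome)),
               ann$order_index)
  ann <- ann[ord, ]
  windows <- list()
  for (chr in unique(ann$chromosome)) {
    genes <- ann$symbol[ann$chromosome == chr]
    if (length(genes) < window_size) {
      pipeline_log("info", sprintf("%s: %d eligible genes < window size %d; no windows",
                                   chr, length(genes), window_size))
      next
    }
    starts <- seq(1L, length(genes) - window_size + 1L, by = stride)
    for (s in starts)
      windows[[length(windows) + 1L]] <-
        list(chromosome = chr, genes = genes[s:(s + window_size - 1L)],
             index = length(windows) + 1L)
  }
  structure(list(windows = windows, window_size = as.integer(window_size),
                 stride = as.integer(stride)),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d genes (stride %d)\n",
              length(x$windows), x$window_size, x$stride))
  invisible(x)
}

#' Unnormalized windowed mean expression (uWME)
#'
#' For each cell and window, the mean TP10k expression over the window's
#' member genes after dropping the `n_top_exclude` largest values — a
#' trimmed mean that damps single highly expressed genes so the window
#' tracks regional dosage. Exactly `n_top_exclude` values are dropped even
#' under ties (ties among equal values cannot change the trimmed mean).
#' Intended for high-complexity (> 1000 detected genes) tumor cells.
#'
#' @param norm A `normalized_matrix` (the TP10k layer is used, not log).
#' @param windows A `window_set`.
#' @param n_top_exclude Number of top expressions dropped per window
#'   (default 5).
#' @return Matrix windows x cells of uWME values.
#' @export
compute_uwme <- function(norm, windows, n_top_exclude = 5L) {
  stopifnot(inherits(norm, "normalized_matrix"), inherits(windows, "window_set"))
  if (windows$window_size <= n_top_exclude)
    stop("value error: window smaller than n_top_exclude + 1", call. = FALSE)
  idx <- lapply(windows$windows, function(w) {
    i <- match(w$genes, norm$genes)
    if (anyNA(i)) stop("window gene absent from expression matrix", call. = FALSE)
    i
  })
  out <- .trimmed_window_means(norm$tp10k, idx, as.integer(n_top_exclude))
  dimnames(out) <- list(paste0("W", seq_along(windows$windows)), norm$cells)
  out
}

#' Non-malignant reference per window, with HLA/6p imputation
#'
#' The reference is a two-level mean of non-malignant uWME: cells are
#' averaged within each patient, then patients are averaged, so no patient
#' dominates by cell count. Windows containing any HLA/6p-flagged gene show
#' strong hematopoietic expression unrelated to tumor copy number, so their
#' reference is imputed with the mean over all non-HLA windows of the
#' cross-patient means; any zero reference is imputed the same way to keep
#' the subsequent division defined.
#'
#' @param uwme_by_patient Named list, one uWME matrix (windows x cells) of
#'   non-malignant cells per patient.
#' @param windows The `window_set` the matrices were computed on.
#' @param annotation A `gene_annotation` (provides the HLA/6p flags).
#' @return Numeric vector of per-window reference values; attribute
#'   `imputed` flags the windows whose value was imputed.
#' @export
build_reference <- function(uwme_by_patient, windows, annotation) {
  uwme_by_patient <- Filter(function(m) ncol(m) > 0, uwme_by_patient)
  if (!length(uwme_by_patient))
    stop("value error: no non-malignant cells to build a reference", call. = FALSE)
  per_patient <- vapply(uwme_by_patient, rowMeans,
                        numeric(length(windows$windows)))
  ref <- rowMeans(as.matrix(per_patient))
  hla_genes <- annotation$symbol[annotation$is_hla_6p]
  is_hla_win <- vapply(windows$windows,
                       function(w) any(w$genes %in% hla_genes), logical(1))
  impute <- is_hla_win | ref == 0
  if (all(impute))
    stop("internal error: every window requires imputation", call. = FALSE)
  fill <- mean(ref[!is_hla_win])
  ref[impute] <- fill
  if (any(ref == 0))
    stop("internal error: zero reference after imputation", call. = FALSE)
  names(ref) <- paste0("W", seq_along(windows$windows))
  attr(ref, "imputed") <- impute
  ref
}

#' Normalize uWME by the non-malignant reference (WME)
#'
#' @param uwme Matrix windows x cells.
#' @param reference Per-window reference from [build_reference()].
#' @return WME matrix: the elementwise quotient per window. A value of 1 is
#'   the neutral (germline-like) copy state.
#' @export
normalize_wme <- function(uwme, reference) {
  if (length(reference) != nrow(uwme))
    stop("reference length must equal number of windows", call. = FALSE)
  if (any(reference <= 0))
    stop("internal error: non-positive reference", call. = FALSE)
  uwme / reference
}

#' Within-cell rank transform of WME (rWME)
#'
#' Converts each cell's WME profile to ranks (ascending, average ties),
#' removing per-cell scale and damping batch effects before embedding.
#'
#' @param wme Matrix windows x cells with at least 2 windows.
#' @return Matrix of the same shape; each column is a permutation of
#'   `1..n_windows` up to average-tie sharing.
#' @export
rank_wme <- function(wme) {
  if (nrow(wme) < 2) stop("value error: need >= 2 windows to rank", call. = FALSE)
  apply(wme, 2, rank)
}

#' Compute the full uWME / reference / WME / rWME stack
#'
#' Convenience wrapper: selects eligible genes, builds windows, computes
#' uWME for the malignant cells (restricted to complexity >
#' `uwme_min_complexity`), builds the non-malignant reference per patient,
#' and derives WME and rWME.
#'
#' @param counts A `count_matrix` (retained cells, WME gene retention
#'   applied).
#' @param annotation A `gene_annotation`.
#' @param metadata A `cell_metadata`.
#' @param window_size,stride,n_top_exclude,dropout_quantile See the stage
#'   functions.
#' @param uwme_min_complexity Malignant cells with complexity at or below
#'   this are excluded from the stack (default 1000).
#' @return List of class `wme_stack`: `window_set`, `cells`, `uwme`,
#'   `reference`, `wme`, `rwme`.
#' @export
compute_wme_stack <- function(counts, annotation, metadata,
                              window_size = 200L, stride = 1L,
                              n_top_exclude = 5L, dropout_quantile = 0.9,
                              uwme_min_complexity = 1000L) {
  eligible <- select_cnv_genes(counts, annotation, dropout_quantile)
  windows <- build_windows(annotation, eligible, window_size, stride)
  if (!length(windows$windows))
    stop("no windows could be constructed", call. = FALSE)
  md <- metadata[match(counts$cells, metadata$barcode), ]
  complexity <- Matrix::colSums(counts$counts > 0)
  mal_cells <- counts$cells[md$is_malignant & complexity > uwme_min_complexity]
  if (!length(mal_cells))
    stop("no malignant cells above the complexity threshold", call. = FALSE)
  norm_all <- normalize_tp10k_log(counts)
  uwme_all <- compute_uwme(norm_all, windows, n_top_exclude)
  uwme_mal <- uwme_all[, mal_cells, drop = FALSE]
  nonmal <- split(counts$cells[!md$is_malignant],
                  md$patient_id[!md$is_malignant])
  uwme_ref <- lapply(nonmal, function(cl) uwme_all[, cl, drop = FALSE])
  reference <- build_reference(uwme_ref, windows, annotation)
  wme <- normalize_wme(uwme_mal, reference)
  structure(list(window_set = windows, cells = mal_cells,
                 uwme = uwme_mal, reference = reference,
                 wme = wme, rwme = rank_wme(wme)),
            class = "wme_stack")
}

#' Write window definitions as a BED-like TSV
#'
#' @param windows A `window_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows <- function(windows, path) {
  df <- do.call(rbind, lapply(windows$windows, function(w)
    data.frame(chromosome = w$chromosome,
               first_gene = w$genes[1],
               last_gene = w$genes[length(w$genes)],
               window_index = w$index)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
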