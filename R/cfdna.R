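#' Purity-correct observed cfDNA copy ratios
#'
#' Deconvolves germline signal from an observed total copy ratio using the
#' sample's tumor purity p:
#' `tcr_corrected = (tcr_observed - (1 - p) * tcr_germline) / p`, with the
#' germline reference ratio fixed at 1. Values below zero (possible when the
#' observed ratio falls under `1 - p` through noise) are kept and flagged,
#' not clipped, so the correction remains the exact inverse of the mixture.
#'
#' @param profile A `copy_ratio_profile`.
#' @return List of class `corrected_copy_ratio`: `sample_id`, `purity`,
#'   `tcr` (named numeric), `negative` (flags).
#' @export
purity_correct_tcr <- function(profile) {
  stopifnot(inherits(profile, "copy_ratio_profile"))
  p <- profile$purity
  corrected <- (profile$tcr - (1 - p)) / p
  neg <- corrected < 0
  if (any(neg))
    pipeline_log("info", sprintf("%d corrected copy ratios are negative (noise)",
                                 sum(neg)))
  structure(list(sample_id = profile$sample_id, purity = p,
                 tcr = corrected, negative = neg),
            class = "corrected_copy_ratio")
}

tcr_values <- function(tcr) {
  if (inherits(tcr, c("copy_ratio_profile", "corrected_copy_ratio"))) tcr$tcr
  else tcr
}

#' Per-cell Kendall correlation between expression and copy ratio
#'
#' For every cell, the tie-corrected Kendall tau between the cell's
#' log-normalized expression and the gene-matched copy-ratio values.
#' Because tau is rank-based and the purity correction is an increasing
#' affine map, observed and corrected ratios give identical correlations.
#'
#' @param expr A `normalized_matrix` (the log2(1+TP10k) layer is used).
#' @param tcr A `copy_ratio_profile`, `corrected_copy_ratio`, or named
#'   numeric vector of gene-level ratios.
#' @return Named numeric vector of tau per cell; attribute `n_genes` gives
#'   the overlap used.
#' @export
cell_copy_correlation <- function(expr, tcr) {
  v <- tcr_values(tcr)
  shared <- intersect(expr$genes, names(v))
  if (length(shared) < 10)
    stop(sprintf("value error: only %d genes shared between expression and copy ratios (need >= 10)",
                 length(shared)), call. = FALSE)
  m <- expr$log2_tp10k[shared, , drop = FALSE]
  tau <- .tau_b_vs_vector(m, as.numeric(v[shared]))
  names(tau) <- expr$cells
  attr(tau, "n_genes") <- length(shared)
  tau
}

#' Per-cell shift in expression/copy-ratio concordance between time points
#'
#' For each cell, `delta = tau_late - tau_early`: positive values mean the
#' cell's expression profile agrees better with the late cfDNA copy-number
#' profile than with the early one. Swapping the two profiles negates delta.
#'
#' @param expr A `normalized_matrix`.
#' @param tcr_early,tcr_late Copy-ratio profiles (observed or corrected).
#' @param metadata Optional `cell_metadata` used for per-sample summaries.
#' @return List of class `concordance_table`: `table` (per-cell data.frame
#'   with `barcode`, `tau_early`, `tau_late`, `delta`, and `sample_id` when
#'   metadata is given) and `summary` (per-sample median and quartiles of
#'   delta).
#' @export
correlation_shift <- function(expr, tcr_early, tcr_late, metadata = NULL) {
  tau_e <- cell_copy_correlation(expr, tcr_early)
  tau_l <- cell_copy_correlation(expr, tcr_late)
  df <- data.frame(barcode = expr$cells,
                   tau_early = as.numeric(tau_e),
                   tau_late = as.numeric(tau_l),
                   delta = as.numeric(tau_l) - as.numeric(tau_e),
                   row.names = NULL)
  summary <- NULL
  if (!is.null(metadata)) {
    df$sample_id <- metadata$sample_id[match(df$barcode, metadata$barcode)]
    summary <- do.call(rbind, lapply(split(df, df$sample_id), function(d)
      data.frame(sample_id = d$sample_id[1], n = nrow(d),
                 q25 = stats::quantile(d$delta, 0.25, names = FALSE),
                 median = stats::median(d$delta),
                 q75 = stats::quantile(d$delta, 0.75, names = FALSE))))
    rownames(summary) <- NULL
  }
  structure(list(table = df, summary = summary), class = "concordance_table")
}

#' Theil-Sen robust slope
#'
#' Median of all pairwise slopes `(y_j - y_i) / (x_j - x_i)`; pairs with
#' duplicated x (undefined slope) are excluded.
#'
#' @param x,y Numeric vectors of equal length, n >= 2.
#' @return The slope estimate.
#' @export
theil_sen_slope <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  n <- length(x)
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  keep <- dx != 0
  if (!any(keep)) stop("value error: all x values identical", call. = FALSE)
  stats::median(dy[keep] / dx[keep])
}

#' Robust slope of module score versus concordance shift, per sample
#'
#' Quantifies how strongly a cell's inflammation score falls as its
#' expression profile aligns with the later copy-number profile: the
#' Theil-Sen slope of score against `delta` within each sample. A negative
#' slope reproduces the signature of an adaptively selected low-inflammation
#' subclone.
#'
#' @param concordance A `concordance_table` with `sample_id` populated.
#' @param scores Data.frame with columns `barcode` and `score` (e.g. the
#'   IFN-gamma response module score).
#' @param sample Optional sample id(s) to restrict to (default: all).
#' @return `data.frame` with columns `sample_id`, `n`, `slope`.
#' @export
ifn_slope_vs_shift <- function(concordance, scores, sample = NULL) {
  df <- concordance$table
  if (is.null(df$sample_id))
    stop("concordance table lacks sample ids; pass metadata to correlation_shift",
         call. = FALSE)
  df$score <- scores$score[match(df$barcode, scores$barcode)]
  df <- df[!is.na(df$score), ]
  if (!is.null(sample)) df <- df[df$sample_id %in% sample, ]
  out <- do.call(rbind, lapply(split(df, df$sample_id), function(d) {
    if (nrow(d) < 3)
      stop(sprintf("value error: sample %s has %d cells with both delta and score (need >= 3)",
                   d$sample_id[1], nrow(d)), call. = FALSE)
    data.frame(sample_id = d$sample_id[1], n = nrow(d),
               slope = theil_sen_slope(d$delta, d$score))
  }))
  rownames(out) <- NULL
  out
}

#' Gene-level concordance between WME change and cfDNA copy-ratio change
#'
#' For every gene (mapped to the mean over the windows containing it), the
#' change in cluster-mean WME between two states is compared with the change
#' in purity-corrected copy ratio between two time points; the summary is
#' the Kendall correlation over genes with its two-sided p-value. A positive
#' correlation says the expression-inferred dosage shift tracks the
#' DNA-measured one.
#'
#' @param wme_mean_a,wme_mean_b Per-window mean WME vectors for the two
#'   states (e.g. the two subclones, or two time points).
#' @param tcr_a,tcr_b Corrected copy-ratio profiles for the two time points.
#' @param windows The `window_set` the WME was computed on.
#' @return List of class `window_delta_concordance`: `table` (per gene:
#'   `gene`, `delta_wme`, `delta_tcr`), `tau`, `p_value`, `n_genes`. When
#'   the copy-ratio change is identically zero the correlation is undefined
#'   and reported as `NA`.
#' @export
window_delta_concordance <- function(wme_mean_a, wme_mean_b, tcr_a, tcr_b,
                                     windows) {
  va <- tcr_values(tcr_a); vb <- tcr_values(tcr_b)
  gene_windows <- list()
  for (wi in seq_along(windows$windows))
    for (g in windows$windows[[wi]]$genes)
      gene_windows[[g]] <- c(gene_windows[[g]], wi)
  genes <- intersect(names(gene_windows), intersect(names(va), names(vb)))
  if (!length(genes))
    stop("value error: no genes shared between windows and copy ratios",
         call. = FALSE)
  dwme_win <- wme_mean_b - wme_mean_a
  delta_wme <- vapply(gene_windows[genes],
                      function(wi) mean(dwme_win[wi]), numeric(1))
  delta_tcr <- vb[genes] - va[genes]
  tab <- data.frame(gene = genes, delta_wme = unname(delta_wme),
                    delta_tcr = unname(delta_tcr), row.names = NULL)
  if (all(delta_tcr == delta_tcr[1]) || all(delta_wme == delta_wme[1])) {
    tau <- NA_real_; p <- NA_real_
  } else {
    ct <- suppressWarnings(stats::cor.test(tab$delta_wme, tab$delta_tcr,
                                           method = "kendall"))
    tau <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(table = tab, tau = tau, p_value = p, n_genes = nrow(tab)),
            class = "window_delta_concordance")
}
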