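# Shared fixture builders and independent brute-force oracles.

# normalized_matrix from a hand-written TP10k layer (bypasses count scaling)
make_norm <- function(tp10k) {
  structure(list(genes = rownames(tp10k), cells = colnames(tp10k),
                 tp10k = tp10k, log2_tp10k = log2(1 + tp10k),
                 layer = "log2_tp10k"),
            class = "normalized_matrix")
}

named_matrix <- function(data, n_genes, n_cells,
                         genes = sprintf("g%02d", seq_len(n_genes)),
                         cells = sprintf("c%02d", seq_len(n_cells))) {
  m <- matrix(data, n_genes, n_cells, dimnames = list(genes, cells))
  m
}

# O(n^2) tie-corrected Kendall tau by explicit pair enumeration
brute_tau <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0) tx <- tx + 1
    if (dy == 0) ty <- ty + 1
    if (dx != 0 && dy != 0) {
      if (sign(dx) == sign(dy)) C <- C + 1 else D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  den <- sqrt(n0 - tx) * sqrt(n0 - ty)
  if (den == 0) return(NA_real_)
  (C - D) / den
}

# O(n^2 w^2) pairwise 1 - tau distance by enumeration
brute_distance_matrix <- function(m) {
  n <- ncol(m)
  d <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tau <- brute_tau(m[, i], m[, j])
    if (is.na(tau)) tau <- 0
    d[i, j] <- d[j, i] <- 1 - tau
  }
  d
}

# independent brute-force WME stack on a toy: explicit loops throughout
brute_wme_stack <- function(tp10k, annotation, eligible, window_size, n_top,
                            malignant_cells, nonmalignant_by_patient) {
  ann <- annotation[match(eligible, annotation$symbol), ]
  windows <- list()
  for (chr in unique(ann$chromosome)) {
    genes <- ann$symbol[ann$chromosome == chr][order(ann$order_index[ann$chromosome == chr])]
    if (length(genes) >= window_size)
      for (s in 1:(length(genes) - window_size + 1))
        windows[[length(windows) + 1]] <- genes[s:(s + window_size - 1)]
  }
  uwme_of <- function(cells) {
    out <- matrix(NA_real_, length(windows), length(cells))
    for (wi in seq_along(windows)) for (ci in seq_along(cells)) {
      v <- tp10k[windows[[wi]], cells[ci]]
      v <- sort(v, decreasing = TRUE)[-(1:n_top)]
      out[wi, ci] <- mean(v)
    }
    out
  }
  uwme_mal <- uwme_of(malignant_cells)
  per_patient <- sapply(nonmalignant_by_patient, function(cl) {
    u <- uwme_of(cl)
    apply(u, 1, mean)
  })
  ref <- apply(as.matrix(per_patient), 1, mean)
  hla <- annotation$symbol[annotation$is_hla_6p]
  is_hla_win <- sapply(windows, function(g) any(g %in% hla))
  fill <- mean(ref[!is_hla_win])
  ref[is_hla_win | ref == 0] <- fill
  wme <- sweep(uwme_mal, 1, ref, "/")
  rwme <- apply(wme, 2, rank)
  list(windows = windows, uwme = uwme_mal, reference = ref,
       wme = wme, rwme = rwme)
}

# small cohort + pipeline config sized for fast unit tests
tiny_sim_config <- function(seed = 7, ...) {
  args <- list(n_genes = 300L, n_chromosomes = 3L,
               n_immune_cells = 30L, n_malignant_cells = 40L,
               library_meanlog = log(1500),
               malignant_library_meanlog = log(4000),
               n_ig_genes = 10L, n_hla_genes = 8L,
               n_ifn_genes = 20L, n_antigen_genes = 12L, n_marker_genes = 6L,
               n_housekeeping_genes = 10L, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

tiny_pipeline_config <- function(seed = 7) {
  pipeline_config(seed = seed,
                  complexity_cutoff = 50L,
                  uwme_min_complexity = 100L,
                  hk_cutoff = 0.5,
                  window_size = 30L,
                  n_clusters = 2L,
                  sim = list(n_genes = 300L, n_chromosomes = 3L,
                             n_immune_cells = 30L, n_malignant_cells = 40L,
                             library_meanlog = log(1500),
                             malignant_library_meanlog = log(4000),
                             n_ig_genes = 10L, n_hla_genes = 8L,
                             n_ifn_genes = 20L, n_antigen_genes = 12L,
                             n_marker_genes = 6L, n_housekeeping_genes = 10L))
}
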