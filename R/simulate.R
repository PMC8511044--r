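#' Configuration for the synthetic longitudinal cohort generator
#'
#' Defines the study conditions the simulator emulates: a single patient
#' sampled at three time points around checkpoint-inhibitor treatment, with
#' two CNV-bearing tumor subclones whose mixing fractions shift over time,
#' shared immune programs, a treatment-induced IFN-gamma module whose
#' upregulation differs by subclone, and matched cfDNA copy-ratio profiles
#' generated under a purity-mixture model.
#'
#' Clone profiles are given as segment lists; genes outside segments carry
#' the germline copy number 2. The default clones implant a focal
#' amplification (copy 4) private to the descendant clone and a broad
#' copy-3 gain private to the ascendant clone, so the two cfDNA profiles are
#' distinguishable in both directions.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_chromosomes Number of chromosomes; genes split evenly (default 4).
#' @param n_immune_cells,n_malignant_cells Cells per time point (defaults
#'   100 and 200).
#' @param time_points Days since first dose per sample; `<= 0` is
#'   pre-treatment (default `c(0, 21, 42)`).
#' @param clone_fractions Matrix time points x clones of malignant-cell
#'   mixing fractions; rows must sum to 1. Default
#'   `rbind(c(.9,.1), c(.5,.5), c(.2,.8))`, a descendant clone replaced by an
#'   ascendant one.
#' @param clones List of clone profiles, each
#'   `list(clone_id, segments = data.frame(chromosome, start, end, copy))`
#'   with starts/ends as within-chromosome order ranks.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   long-tailed per-gene baseline expression weights (defaults 0, 1.25).
#' @param dispersion Negative-binomial size parameter shared by all genes
#'   (default 2; smaller = noisier, more dropout).
#' @param library_meanlog,library_sdlog Log-normal parameters of per-cell
#'   library size for immune cells (defaults `log(2000)`, 0.3).
#' @param malignant_library_meanlog Log-mean library size for malignant
#'   cells (default `log(8000)`): tumor cells carry far more RNA than
#'   lymphocytes, and CNV inference is restricted to high-complexity
#'   (> 1000 detected genes) tumor cells.
#' @param ifn_effect Matrix clones x time points of fold-changes applied to
#'   the designated IFN-gamma response genes in malignant cells. Default:
#'   the descendant (immunogenic) clone responds strongly at the early
#'   post-treatment point, the ascendant clone barely.
#' @param immune_ifn_effect Fold-change per time point applied to IFN genes
#'   in immune cells (default `c(1, 2, 1.2)`).
#' @param marker_boost Fold-change applied to each immune cell type's marker
#'   genes (default 5).
#' @param n_ig_genes,n_hla_genes Sizes of the contiguous immunoglobulin and
#'   HLA/6p flagged blocks placed on the last chromosome (defaults 50, 40).
#' @param n_ifn_genes,n_antigen_genes,n_marker_genes,n_housekeeping_genes
#'   Sizes of the designated IFN-gamma response, antigen presentation,
#'   per-cell-type marker, and housekeeping gene programs (defaults 60, 40,
#'   15, 30).
#' @param pbl_fraction Fraction of immune cells per time point labeled as
#'   peripheral-blood (PBL) compartment (default 0 = CSF only).
#' @param cfdna_purity Tumor purity of the matched cfDNA sample per time
#'   point (default `c(0.55, 0.3, 0.65)`: purity dips at response, rises at
#'   progression).
#' @param cfdna_noise_sd Gaussian noise s.d. on observed copy ratios
#'   (default 0.05).
#' @param seed Master seed for the generator (default 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_chromosomes = 4L,
                       n_immune_cells = 100L,
                       n_malignant_cells = 200L,
                       time_points = c(0L, 21L, 42L),
                       clone_fractions = rbind(c(0.9, 0.1),
                                               c(0.5, 0.5),
                                               c(0.2, 0.8)),
                       clones = NULL,
                       baseline_meanlog = 0,
                       baseline_sdlog = 1.25,
                       dispersion = 2,
                       library_meanlog = log(2000),
                       library_sdlog = 0.3,
                       malignant_library_meanlog = log(8000),
                       ifn_effect = rbind(c(1, 2.5, 1.6),
                                          c(1, 1.3, 1.1)),
                       immune_ifn_effect = c(1, 2, 1.2),
                       marker_boost = 5,
                       n_ig_genes = 50L,
                       n_hla_genes = 40L,
                       n_ifn_genes = 60L,
                       n_antigen_genes = 40L,
                       n_marker_genes = 15L,
                       n_housekeeping_genes = 30L,
                       pbl_fraction = 0,
                       cfdna_purity = c(0.55, 0.3, 0.65),
                       cfdna_noise_sd = 0.05,
                       seed = 1L) {
  if (is.null(clones)) {
    per_chr <- n_genes %/% n_chromosomes
    seg_len <- max(1L, round(0.15 * per_chr))
    clones <- list(
      list(clone_id = "clone1",
           segments = data.frame(chromosome = "chr3",
                                 start = 2L * seg_len + 1L, end = 4L * seg_len,
                                 copy = 4)),
      list(clone_id = "clone2",
           segments = data.frame(chromosome = c("chr1", "chr2"),
                                 start = c(seg_len + 1L, seg_len + 1L),
                                 end = c(4L * seg_len, 4L * seg_len),
                                 copy = c(3, 3)))
    )
  }
  clone_fractions <- as.matrix(clone_fractions)
  if (nrow(clone_fractions) != length(time_points))
    stop("value error: clone_fractions must have one row per time point", call. = FALSE)
  if (ncol(clone_fractions) != length(clones))
    stop("value error: clone_fractions must have one column per clone", call. = FALSE)
  if (any(abs(rowSums(clone_fractions) - 1) > 1e-8))
    stop("value error: clone fractions must sum to 1 at every time point", call. = FALSE)
  if (any(clone_fractions < 0))
    stop("value error: clone fractions must be non-negative", call. = FALSE)
  ifn_effect <- as.matrix(ifn_effect)
  if (!all(dim(ifn_effect) == c(length(clones), length(time_points))))
    stop("value error: ifn_effect must be clones x time points", call. = FALSE)
  if (length(immune_ifn_effect) != length(time_points))
    stop("value error: immune_ifn_effect must have one entry per time point", call. = FALSE)
  if (length(cfdna_purity) != length(time_points))
    stop("value error: cfdna_purity must have one entry per time point", call. = FALSE)
  stopifnot(n_genes > 0, n_chromosomes > 0, n_immune_cells >= 0,
            n_malignant_cells > 0, dispersion > 0, marker_boost > 0)
  structure(as.list(environment())[c(
    "n_genes", "n_chromosomes", "n_immune_cells", "n_malignant_cells",
    "time_points", "clone_fractions", "clones", "baseline_meanlog",
    "baseline_sdlog", "dispersion", "library_meanlog", "library_sdlog",
    "malignant_library_meanlog",
    "ifn_effect", "immune_ifn_effect", "marker_boost", "n_ig_genes",
    "n_hla_genes", "n_ifn_genes", "n_antigen_genes", "n_marker_genes",
    "n_housekeeping_genes", "pbl_fraction", "cfdna_purity", "cfdna_noise_sd",
    "seed")],
    class = "sim_config")
}

# expand a clone's segment list into a per-gene copy-number vector
clone_copy_vector <- function(clone, annotation) {
  cn <- rep(2, nrow(annotation))
  segs <- clone$segments
  if (!is.null(segs) && nrow(segs)) {
    for (i in seq_len(nrow(segs))) {
      hit <- annotation$chromosome == segs$chromosome[i] &
        annotation$order_index >= segs$start[i] &
        annotation$order_index <= segs$end[i]
      cn[hit] <- segs$copy[i]
    }
  }
  stats::setNames(cn, annotation$symbol)
}

# deterministic composition: allocate n cells to fractions, largest-remainder
allocate_counts <- function(n, fractions) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a longitudinal single-cell cohort with implanted CNV subclones
#'
#' Gene baseline expression weights are drawn from a long-tailed log-normal;
#' a malignant cell of clone c at time t has expected relative expression
#' `baseline x copy(g, c)/2 x ifn_effect(c, t)` on IFN genes; immune cells
#' use the baseline with cell-type marker boosts and a shared IFN response.
#' Per-cell library sizes are log-normal and counts are drawn from a
#' gamma-Poisson (negative binomial) model. Fully reproducible from the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return List with elements `counts` (`count_matrix`), `annotation`
#'   (`gene_annotation`), `metadata` (`cell_metadata`) and `truth` (ground
#'   truth: per-cell clone/type labels, per-gene clone copy numbers,
#'   designated signature gene sets, configured clone fractions, and the
#'   true tumor copy ratio per gene and time point).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n_tp <- length(cfg$time_points)
  n_clones <- length(cfg$clones)
  per_chr <- cfg$n_genes %/% cfg$n_chromosomes
  n_genes <- per_chr * cfg$n_chromosomes

  chrom <- rep(paste0("chr", seq_len(cfg$n_chromosomes)), each = per_chr)
  order_index <- rep(seq_len(per_chr), cfg$n_chromosomes)
  symbol <- sprintf("G%05d", seq_len(n_genes))
  last_chr <- paste0("chr", cfg$n_chromosomes)
  is_hla <- chrom == last_chr & order_index <= cfg$n_hla_genes
  is_ig <- chrom == last_chr &
    order_index > per_chr - cfg$n_ig_genes & order_index <= per_chr
  annotation <- gene_annotation(symbol, chrom, order_index, is_ig, is_hla)

  baseline <- stats::rlnorm(n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)
  names(baseline) <- symbol

  copy <- vapply(cfg$clones, clone_copy_vector, numeric(n_genes),
                 annotation = annotation)
  colnames(copy) <- vapply(cfg$clones, `[[`, "", "clone_id")

  # designated gene programs; IFN genes drawn from moderately expressed genes
  # outside the flagged blocks so fold-changes are observable at UMI depth
  in_segment <- rowSums(copy != 2) > 0
  plain <- which(!is_ig & !is_hla & !in_segment)
  expressed <- plain[baseline[plain] >= stats::median(baseline)]
  n_pick <- cfg$n_ifn_genes + cfg$n_antigen_genes + 4L * cfg$n_marker_genes
  if (length(expressed) < n_pick)
    stop("value error: too few well-expressed genes outside flagged blocks to place the gene programs; reduce program sizes or raise n_genes",
         call. = FALSE)
  picks <- sample(expressed, n_pick)
  cuts <- cumsum(c(cfg$n_ifn_genes, cfg$n_antigen_genes,
                   rep(cfg$n_marker_genes, 4)))
  grp <- function(i) symbol[picks[(c(0, cuts)[i] + 1):cuts[i]]]
  sigs <- list(
    ifn_response = grp(1),
    antigen_presentation = grp(2),
    markers = list(CD4T = grp(3), CD8T = grp(4), NK = grp(5), myeloid = grp(6))
  )
  hk_pool <- setdiff(plain[order(baseline[plain], decreasing = TRUE)], picks)
  if (length(hk_pool) < cfg$n_housekeeping_genes)
    stop("value error: too few genes left for the housekeeping program", call. = FALSE)
  sigs$housekeeping <- symbol[hk_pool[seq_len(cfg$n_housekeeping_genes)]]
  ifn_idx <- match(sigs$ifn_response, symbol)

  immune_types <- names(sigs$markers)
  cells <- list(); meta <- list()
  for (t in seq_len(n_tp)) {
    n_mal <- allocate_counts(cfg$n_malignant_cells, cfg$clone_fractions[t, ])
    clone_lab <- rep(colnames(copy), n_mal)
    type_lab <- c(rep("tumor", sum(n_mal)),
                  rep(immune_types, allocate_counts(cfg$n_immune_cells,
                                                    rep(1 / 4, 4))))
    clone_lab <- c(clone_lab, rep(NA_character_, length(type_lab) - length(clone_lab)))
    n_cells <- length(type_lab)
    comp <- rep("CSF", n_cells)
    imm <- which(type_lab != "tumor")
    n_pbl <- round(cfg$pbl_fraction * length(imm))
    # random assignment so compartments share cell-type composition
    if (n_pbl > 0) comp[sample(imm, n_pbl)] <- "PBL"
    meta[[t]] <- data.frame(sample_id = paste0("P1-T", t),
                            days = cfg$time_points[t],
                            compartment = comp,
                            cell_type = type_lab, clone = clone_lab,
                            stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  meta$barcode <- sprintf("C%05d", seq_len(nrow(meta)))
  meta$sample_id <- ifelse(meta$compartment == "PBL",
                           paste0(meta$sample_id, "-PBL"), meta$sample_id)

  tp_of <- match(meta$days, cfg$time_points)
  lib_meanlog <- ifelse(meta$cell_type == "tumor",
                        cfg$malignant_library_meanlog, cfg$library_meanlog)
  lib <- stats::rlnorm(nrow(meta), lib_meanlog, cfg$library_sdlog)
  counts <- matrix(0L, n_genes, nrow(meta))
  for (i in seq_len(nrow(meta))) {
    w <- baseline
    t <- tp_of[i]
    if (!is.na(meta$clone[i])) {
      ci <- match(meta$clone[i], colnames(copy))
      w <- w * copy[, ci] / 2
      w[ifn_idx] <- w[ifn_idx] * cfg$ifn_effect[ci, t]
    } else {
      w[match(sigs$markers[[meta$cell_type[i]]], symbol)] <-
        w[match(sigs$markers[[meta$cell_type[i]]], symbol)] * cfg$marker_boost
      w[ifn_idx] <- w[ifn_idx] * cfg$immune_ifn_effect[t]
    }
    mu <- lib[i] * w / sum(w)
    counts[, i] <- stats::rnbinom(n_genes, mu = mu, size = cfg$dispersion)
  }
  rownames(counts) <- symbol
  colnames(counts) <- meta$barcode

  cm <- count_matrix(counts)
  md <- cell_metadata(meta$barcode, meta$sample_id, "P1", meta$compartment,
                      meta$days, meta$cell_type, meta$cell_type == "tumor")

  true_tcr <- lapply(seq_len(n_tp), function(t)
    stats::setNames(as.vector(copy %*% cfg$clone_fractions[t, ] / 2), symbol))
  names(true_tcr) <- paste0("T", seq_len(n_tp))

  truth <- list(clone = stats::setNames(meta$clone, meta$barcode),
                cell_type = stats::setNames(meta$cell_type, meta$barcode),
                copy_number = copy,
                signatures = sigs,
                clone_fractions = cfg$clone_fractions,
                time_points = cfg$time_points,
                true_tcr = true_tcr,
                baseline = baseline,
                config = cfg)
  list(counts = cm, annotation = annotation, metadata = md, truth = truth)
}

#' Simulate a matched cfDNA copy-ratio profile under the purity mixture
#'
#' The true tumor copy ratio per gene at a time point is the clone-fraction-
#' weighted mean of clone copy numbers over 2; the observed ratio mixes it
#' with the germline (ratio 1) according to sample purity and adds Gaussian
#' noise, clipped at zero:
#' `tcr_obs = p * tcr_true + (1 - p) * 1 + N(0, noise_sd)`.
#'
#' @param truth `truth` element returned by [simulate_cohort()].
#' @param time_point Index of the time point (1-based).
#' @param purity Tumor fraction in (0, 1].
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed Optional seed for the noise draw.
#' @return A `copy_ratio_profile`.
#' @export
simulate_cfdna <- function(truth, time_point, purity, noise_sd = 0, seed = NULL) {
  if (!is.numeric(purity) || purity <= 0 || purity > 1)
    stop("value error: purity must lie in (0, 1]", call. = FALSE)
  tcr_true <- truth$true_tcr[[time_point]]
  draw <- function() {
    obs <- purity * tcr_true + (1 - purity) +
      if (noise_sd > 0) stats::rnorm(length(tcr_true), 0, noise_sd) else 0
    pmax(obs, 0)
  }
  obs <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  copy_ratio_profile(paste0("cfDNA-T", time_point), purity,
                     stats::setNames(obs, names(tcr_true)))
}
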