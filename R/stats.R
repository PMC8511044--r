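#' Assign treatment phases to samples
#'
#' Days since the first checkpoint-inhibitor dose map to three phases:
#' `pre` (days <= 0, day 0 sampled before administration), `early_post`
#' (0 < days < boundary) and `late_post` (days >= boundary), with the
#' boundary at 30 days.
#'
#' @param metadata A `cell_metadata`.
#' @param boundary Phase boundary in days (default 30).
#' @return `data.frame` with one row per sample: `sample_id`,
#'   `days_since_first_dose`, `phase`.
#' @export
assign_phase <- function(metadata, boundary = 30L) {
  smp <- unique(metadata[c("sample_id", "days_since_first_dose")])
  if (anyDuplicated(smp$sample_id))
    stop("sample with inconsistent days_since_first_dose: ",
         smp$sample_id[duplicated(smp$sample_id)][1], call. = FALSE)
  if (anyNA(smp$days_since_first_dose))
    stop("missing days for sample ",
         smp$sample_id[is.na(smp$days_since_first_dose)][1], call. = FALSE)
  d <- smp$days_since_first_dose
  smp$phase <- ifelse(d <= 0, "pre",
                      ifelse(d < boundary, "early_post", "late_post"))
  rownames(smp) <- NULL
  smp
}

#' Wilcoxon rank-sum test
#'
#' Exact null distribution for small samples without ties, normal
#' approximation with continuity and tie correction otherwise (the behavior
#' of `stats::wilcox.test`).
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param sided `"two"`, `"one-greater"` (x > y) or `"one-less"`.
#' @return List with `statistic` (W) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y, sided = c("two", "one-greater", "one-less")) {
  sided <- match.arg(sided)
  if (!length(x) || !length(y))
    stop("value error: both groups must be non-empty", call. = FALSE)
  alt <- switch(sided, two = "two.sided", `one-greater` = "greater",
                `one-less` = "less")
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = alt))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Cohen's d effect size (pooled and pre-treatment-s.d. variants)
#'
#' `pooled`: `(mean(x) - mean(y)) / sd_pooled` with the usual
#' degrees-of-freedom-weighted pooled standard deviation. `pre_sd`
#' (the paired variant d_pair): the mean difference normalized by the
#' standard deviation of the second (reference, pre-treatment) group.
#'
#' @param x,y Numeric vectors; `y` is the reference group in `pre_sd` mode.
#' @param mode `"pooled"` or `"pre_sd"`.
#' @return The effect size.
#' @export
cohens_d <- function(x, y, mode = c("pooled", "pre_sd")) {
  mode <- match.arg(mode)
  if (mode == "pooled") {
    if (length(x) < 2 || length(y) < 2)
      stop("value error: pooled mode needs >= 2 per group", call. = FALSE)
    sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    if (sp == 0) stop("value error: zero pooled standard deviation", call. = FALSE)
    (mean(x) - mean(y)) / sp
  } else {
    s <- stats::sd(y)
    if (is.na(s) || s == 0)
      stop("value error: reference group standard deviation is zero", call. = FALSE)
    (mean(x) - mean(y)) / s
  }
}

#' Kendall tau correlation test
#'
#' Tie-corrected tau with a two-sided p-value: exact for small samples
#' without ties, asymptotic otherwise (via `stats::cor.test`).
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return List with `tau` and `p_value`.
#' @export
kendall_tau_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("value error: need paired vectors with n >= 3", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("value error: tau undefined for a constant vector", call. = FALSE)
  ht <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  list(tau = unname(ht$estimate), p_value = ht$p.value)
}

#' Bonferroni adjustment
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return `pmin(1, m * p)` where m is the number of tests.
#' @export
bonferroni_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("value error: p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Phase-grouped sample-level comparisons with inclusion thresholds
#'
#' Aggregates per-cell values to per-sample means after excluding samples
#' with too few contributing cells (strict `>` threshold, per the relevant
#' comparison kind: 20 for T-cell abundance, 10 for CD8 proliferation, 5
#' for module-score means), then reports a Wilcoxon rank-sum test and
#' Cohen's d for every pair of phases. Comparisons with fewer than two
#' samples in a group are skipped with a report entry.
#'
#' @param values `data.frame` with columns `barcode` and `value` (per-cell),
#'   or with columns `sample_id` and `value` (already per-sample).
#' @param metadata A `cell_metadata`.
#' @param min_cells Strict lower bound on contributing cells per sample
#'   (default 5).
#' @param boundary Phase boundary in days (default 30).
#' @param d_mode Effect size variant (see [cohens_d()]); `pre_sd` uses the
#'   chronologically earlier phase as reference.
#' @return `data.frame` with one row per contrast: groups, n per group,
#'   Wilcoxon W and p, effect size, and a `status` of "ok" or "skipped".
#' @export
sample_group_compare <- function(values, metadata, min_cells = 5L,
                                 boundary = 30L, d_mode = "pooled") {
  phases <- assign_phase(metadata, boundary)
  if (is.null(values$value) && !is.null(values$score))
    values$value <- values$score  # module-score tables plug in directly
  if (!is.null(values$barcode)) {
    values$sample_id <- metadata$sample_id[match(values$barcode, metadata$barcode)]
    agg <- do.call(rbind, lapply(split(values, values$sample_id), function(d)
      data.frame(sample_id = d$sample_id[1], n_cells = nrow(d),
                 value = mean(d$value))))
    excluded <- agg$sample_id[agg$n_cells <= min_cells]
    if (length(excluded))
      pipeline_log("info", sprintf("%d sample(s) below cell threshold excluded",
                                   length(excluded)))
    agg <- agg[agg$n_cells > min_cells, ]
  } else {
    agg <- data.frame(sample_id = values$sample_id, value = values$value)
  }
  agg$phase <- phases$phase[match(agg$sample_id, phases$sample_id)]
  phase_order <- c("pre", "early_post", "late_post")
  present <- intersect(phase_order, unique(agg$phase))
  out <- list()
  if (length(present) >= 2) {
    for (i in seq_len(length(present) - 1)) for (j in (i + 1):length(present)) {
      g1 <- agg$value[agg$phase == present[j]]  # later phase first: d > 0 = increase
      g2 <- agg$value[agg$phase == present[i]]
      row <- data.frame(group1 = present[j], group2 = present[i],
                        n1 = length(g1), n2 = length(g2),
                        statistic = NA_real_, p_value = NA_real_,
                        effect_size = NA_real_, effect_mode = d_mode,
                        status = "skipped", stringsAsFactors = FALSE)
      if (length(g1) >= 2 && length(g2) >= 2) {
        wt <- wilcoxon_rank_sum(g1, g2, "two")
        row$statistic <- wt$statistic
        row$p_value <- wt$p_value
        row$effect_size <- tryCatch(cohens_d(g1, g2, d_mode), error = function(e) NA_real_)
        row$status <- "ok"
      }
      out[[length(out) + 1]] <- row
    }
  }
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(group1 = character(), group2 = character(), n1 = integer(),
               n2 = integer(), statistic = numeric(), p_value = numeric(),
               effect_size = numeric(), effect_mode = character(),
               status = character())
  rownames(out) <- NULL
  out
}

#' CSF-versus-PBL compartment comparison at matched depth
#'
#' Both compartments are downsampled to a fixed per-cell UMI total
#' (default 500) to remove depth confounding, renormalized, and scored for
#' each signature over the combined cell subset; CSF and PBL cells are then
#' compared per signature and time point with a Wilcoxon rank-sum test and
#' Cohen's d (CSF minus PBL).
#'
#' @param counts A `count_matrix` holding both compartments.
#' @param metadata A `cell_metadata`.
#' @param signatures A `gene_set_collection`.
#' @param target_umis Downsampling target (default 500).
#' @param n_bins,n_ctrl Module-score parameters.
#' @param seed Seed for downsampling and control sampling.
#' @return `data.frame`: one row per signature x matched time point with
#'   group sizes, Wilcoxon p and Cohen's d.
#' @export
compartment_compare <- function(counts, metadata, signatures,
                                target_umis = 500L, n_bins = 25L,
                                n_ctrl = 100L, seed = 1L) {
  md <- metadata[match(counts$cells, metadata$barcode), ]
  days_csf <- unique(md$days_since_first_dose[md$compartment == "CSF"])
  days_pbl <- unique(md$days_since_first_dose[md$compartment == "PBL"])
  matched <- intersect(days_csf, days_pbl)
  if (!length(matched))
    stop("value error: no matched CSF/PBL time points", call. = FALSE)
  keep <- md$days_since_first_dose %in% matched
  cm <- count_matrix(counts$counts[, keep, drop = FALSE])
  md <- md[keep, ]
  ds <- downsample_cell_umis(cm, target = target_umis, seed = seed)
  norm <- normalize_tp10k_log(ds)
  out <- list()
  for (sig in names(signatures)) {
    sc <- module_score(norm, signatures[[sig]], n_bins = n_bins,
                       n_ctrl = n_ctrl, seed = seed)
    for (d in sort(matched)) {
      csf <- sc$score[md$compartment == "CSF" & md$days_since_first_dose == d]
      pbl <- sc$score[md$compartment == "PBL" & md$days_since_first_dose == d]
      if (length(csf) < 2 || length(pbl) < 2) next
      wt <- wilcoxon_rank_sum(csf, pbl, "two")
      out[[length(out) + 1]] <- data.frame(
        signature = sig, days_since_first_dose = d,
        n_csf = length(csf), n_pbl = length(pbl),
        statistic = wt$statistic, p_value = wt$p_value,
        effect_size = cohens_d(csf, pbl, "pooled"))
    }
  }
  if (!length(out))
    stop("value error: no comparable compartment groups", call. = FALSE)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
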