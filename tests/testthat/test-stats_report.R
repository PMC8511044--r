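phase_metadata <- function(days) {
  n <- length(days)
  cell_metadata(sprintf("b%03d", 1:n), sprintf("S%02d", 1:n), "P1", "CSF",
                days, "tumor", TRUE)
}

test_that("treatment phases split at day 0 and day 30", {
  ph <- assign_phase(phase_metadata(c(-3L, 0L, 12L, 29L, 30L, 45L)))
  expect_equal(ph$phase, c("pre", "pre", "early_post", "early_post",
                           "late_post", "late_post"))
})

test_that("Wilcoxon rank-sum matches exhaustive enumeration for small n", {
  # (1,2,3) vs (4,5,6): the most extreme of C(6,3) = 20 arrangements, doubled
  wt <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), "two")
  expect_equal(wt$p_value, 0.1)
  expect_equal(wt$statistic, 0)

  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3), "two")$p_value, 1)

  # exhaustive-enumeration oracle for n = 4 vs 4 without ties
  x <- c(0.3, 1.1, 2.7, 3.9); y <- c(0.9, 1.8, 4.5, 6.1)
  perms <- combn(8, 4)
  pool <- c(x, y)
  w_obs <- sum(rank(pool)[1:4]) - 4 * 5 / 2
  w_all <- apply(perms, 2, function(idx) sum(rank(pool)[idx]) - 10)
  p_oracle <- mean(abs(w_all - 8) >= abs(w_obs - 8))  # center = n1*n2/2 = 8
  expect_equal(wilcoxon_rank_sum(x, y, "two")$p_value, p_oracle)

  # large one-sided shift attains the minimal p for the group sizes
  expect_equal(wilcoxon_rank_sum(c(101, 102, 103), c(1, 2, 3),
                                 "one-greater")$p_value, 1 / 20)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("Cohen's d variants match hand arithmetic and antisymmetry", {
  expect_equal(cohens_d(c(1, 2, 3), c(4, 5, 6), "pooled"), -3)
  expect_equal(cohens_d(c(1, 2, 3), c(3, 2, 1), "pooled"), 0)
  # reference-sd variant: means differ by 4, reference sd = 2
  y <- c(1, 3, 5) / sqrt(var(c(1, 3, 5))) * 2
  x <- y + 4
  expect_equal(cohens_d(x, y, "pre_sd"), 2)
  set.seed(1)
  a <- rnorm(10); b <- rnorm(12, 1)
  expect_equal(cohens_d(a, b, "pooled"), -cohens_d(b, a, "pooled"))
  expect_error(cohens_d(c(1, 1), c(1, 1), "pooled"), "zero pooled")
  expect_error(cohens_d(1:3, c(2, 2, 2), "pre_sd"), "reference")
})

test_that("Kendall test reports tie-corrected tau with calibrated p-values", {
  expect_equal(kendall_tau_test(1:6, (1:6)^2)$tau, 1)
  expect_equal(kendall_tau_test(c(1, 2, 3), c(1, 3, 2))$tau, 1 / 3)
  expect_error(kendall_tau_test(rep(1, 5), 1:5), "constant")

  # under independence the p-value is uniform (KS over repeats)
  set.seed(20)
  ps <- replicate(200, kendall_tau_test(rnorm(40), rnorm(40))$p_value)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("Bonferroni multiplies and caps", {
  expect_equal(bonferroni_adjust(rep(0.01, 5)), rep(0.05, 5))
  expect_equal(bonferroni_adjust(c(0.5, 0.2, 0.9)), c(1, 0.6, 1))
  expect_equal(bonferroni_adjust(0.37), 0.37)          # m = 1 identity
  p <- c(0.001, 0.04, 0.7)
  expect_true(all(bonferroni_adjust(p) >= p))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "p-values")
})

test_that("sample comparisons respect strict cell-count inclusion", {
  # 6 samples: 3 pre, 3 late; one pre sample has only 4 cells (<= 5 excluded)
  n_cells <- c(10, 10, 4, 10, 10, 10)
  days <- c(-5L, 0L, -1L, 40L, 45L, 50L)
  md <- do.call(rbind, lapply(1:6, function(i)
    data.frame(barcode = sprintf("s%d_%02d", i, seq_len(n_cells[i])),
               sample_id = sprintf("S%02d", i), patient_id = "P1",
               compartment = "CSF", days_since_first_dose = days[i],
               cell_type = "tumor", is_malignant = TRUE)))
  md <- cell_metadata(md$barcode, md$sample_id, md$patient_id, md$compartment,
                      md$days_since_first_dose, md$cell_type, md$is_malignant)
  set.seed(3)
  vals <- data.frame(barcode = md$barcode,
                     value = rnorm(nrow(md)) +
                       ifelse(md$days_since_first_dose > 0, 2, 0))
  res <- suppressMessages(sample_group_compare(vals, md, min_cells = 5))
  expect_equal(nrow(res), 1L)
  expect_equal(res$n1 + res$n2, 5L)  # the 4-cell sample is gone

  # with all samples passing, the comparison reduces to a direct rank-sum
  res_all <- suppressMessages(sample_group_compare(vals, md, min_cells = 3))
  agg <- tapply(vals$value, md$sample_id[match(vals$barcode, md$barcode)], mean)
  direct <- wilcoxon_rank_sum(agg[4:6], agg[1:3], "two")
  expect_equal(res_all$p_value, direct$p_value)
  expect_equal(res_all$n1, 3L)
})

test_that("a single-sample group yields a skipped comparison entry", {
  md <- phase_metadata(c(-2L, -1L, 40L))
  vals <- data.frame(sample_id = md$sample_id, value = c(1, 2, 9))
  res <- sample_group_compare(vals, md)
  expect_equal(res$status, "skipped")
  expect_true(is.na(res$p_value))
})

test_that("compartment comparison detects an implanted CSF shift", {
  cfg <- tiny_sim_config(seed = 31, pbl_fraction = 0.5,
                         n_immune_cells = 80L, n_malignant_cells = 10L,
                         time_points = 10L,
                         clone_fractions = matrix(c(0.5, 0.5), 1),
                         ifn_effect = matrix(1, 2, 1), immune_ifn_effect = 1,
                         cfdna_purity = 0.5)
  sim <- simulate_cohort(cfg)
  counts <- as.matrix(sim$counts$counts)
  sig <- sim$truth$signatures$antigen_presentation
  md <- sim$metadata
  csf <- md$barcode[md$compartment == "CSF"]
  counts[sig, csf] <- counts[sig, csf] * 4L   # CSF-only inflammation
  sets <- gene_set_collection(list(ag = sig))
  res <- suppressWarnings(compartment_compare(
    count_matrix(counts), md, sets, target_umis = 300, n_bins = 8,
    n_ctrl = 20, seed = 2))
  expect_lt(res$p_value, 0.01)
  expect_gt(res$effect_size, 0)
})

test_that("downsampling removes a depth-confounded compartment difference", {
  # identical expression program, but CSF cells sequenced ~5x deeper than
  # PBL cells: two generator runs sharing the seed (hence gene baselines and
  # programs) that differ only in library size
  base_args <- list(seed = 33, n_immune_cells = 60L, n_malignant_cells = 10L,
                    time_points = 10L, clone_fractions = matrix(c(0.5, 0.5), 1),
                    ifn_effect = matrix(1, 2, 1), immune_ifn_effect = 1,
                    cfdna_purity = 0.5)
  deep <- simulate_cohort(do.call(tiny_sim_config,
                                  c(base_args, library_meanlog = log(3000))))
  shallow <- simulate_cohort(do.call(tiny_sim_config,
                                     c(base_args, library_meanlog = log(600))))
  expect_identical(deep$truth$signatures, shallow$truth$signatures)

  imm_d <- deep$metadata$barcode[!deep$metadata$is_malignant]
  imm_s <- shallow$metadata$barcode[!shallow$metadata$is_malignant]
  cts <- cbind(as.matrix(deep$counts$counts)[, imm_d],
               as.matrix(shallow$counts$counts)[, imm_s])
  colnames(cts) <- c(paste0("CSF_", imm_d), paste0("PBL_", imm_s))
  md <- cell_metadata(colnames(cts),
                      rep(c("S-CSF", "S-PBL"), c(length(imm_d), length(imm_s))),
                      "P1",
                      rep(c("CSF", "PBL"), c(length(imm_d), length(imm_s))),
                      10L, "CD8T", FALSE)
  sig <- deep$truth$signatures$ifn_response
  sets <- gene_set_collection(list(ifn = sig))

  # without depth adjustment the raw signature mean differs spuriously:
  # deeper cells drop out less, inflating mean log expression
  norm_raw <- normalize_tp10k_log(count_matrix(cts))
  raw <- colMeans(norm_raw$log2_tp10k[sig, ])
  raw_p <- wilcoxon_rank_sum(raw[md$compartment == "CSF"],
                             raw[md$compartment == "PBL"], "two")$p_value
  expect_lt(raw_p, 0.01)

  # equalizing depth removes it, both for the raw mean ...
  norm_ds <- normalize_tp10k_log(
    downsample_cell_umis(count_matrix(cts), 300, seed = 2))
  adj <- colMeans(norm_ds$log2_tp10k[sig, ])
  adj_p <- wilcoxon_rank_sum(adj[md$compartment == "CSF"],
                             adj[md$compartment == "PBL"], "two")$p_value
  expect_gt(adj_p, 0.05)

  # ... and for the full compartment comparison
  res <- suppressWarnings(compartment_compare(
    count_matrix(cts), md, sets, target_umis = 300, n_bins = 8,
    n_ctrl = 20, seed = 2))
  expect_gt(res$p_value, 0.05)
})
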