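test_that("invalid clone fractions and purities are rejected", {
  expect_error(sim_config(clone_fractions = rbind(c(0.6, 0.6), c(0.5, 0.5),
                                                  c(0.5, 0.5))),
               "sum to 1")
  sim <- simulate_cohort(tiny_sim_config())
  expect_error(simulate_cfdna(sim$truth, 1, purity = 0), "purity")
  expect_error(simulate_cfdna(sim$truth, 1, purity = 1.2), "purity")
})

test_that("the generator is deterministic in its seed", {
  a <- simulate_cohort(tiny_sim_config(seed = 9))
  b <- simulate_cohort(tiny_sim_config(seed = 9))
  expect_identical(as.matrix(a$counts$counts), as.matrix(b$counts$counts))
  expect_identical(a$truth$clone, b$truth$clone)
  c2 <- simulate_cohort(tiny_sim_config(seed = 10))
  expect_false(identical(as.matrix(a$counts$counts), as.matrix(c2$counts$counts)))
})

test_that("per-time-point clone composition matches configured fractions", {
  sim <- simulate_cohort(tiny_sim_config())
  md <- sim$metadata
  cfg <- sim$truth$config
  for (t in seq_along(cfg$time_points)) {
    cl <- sim$truth$clone[md$barcode[md$is_malignant &
                                       md$days_since_first_dose == cfg$time_points[t]]]
    frac <- mean(cl == "clone1")
    expect_lt(abs(frac - cfg$clone_fractions[t, 1]),
              1 / cfg$n_malignant_cells + 1e-12)
  }
})

test_that("mean TP10k in an amplified segment scales with copy number", {
  # one clone carries a 100-gene copy-4 segment on chr1; TP10k ratio ~ 2x
  clones <- list(
    list(clone_id = "cloneA", segments = data.frame(chromosome = character(),
                                                    start = integer(),
                                                    end = integer(),
                                                    copy = numeric())),
    list(clone_id = "cloneB", segments = data.frame(chromosome = "chr1",
                                                    start = 101L, end = 200L,
                                                    copy = 4)))
  cfg <- sim_config(n_genes = 1200L, n_chromosomes = 3L,
                    n_immune_cells = 0L, n_malignant_cells = 500L,
                    time_points = 0L, clone_fractions = matrix(c(0.5, 0.5), 1),
                    clones = clones,
                    ifn_effect = matrix(1, 2, 1), immune_ifn_effect = 1,
                    cfdna_purity = 0.5, seed = 21)
  sim <- simulate_cohort(cfg)
  seg <- sim$annotation$symbol[sim$annotation$chromosome == "chr1" &
                                 sim$annotation$order_index %in% 101:200]
  norm <- normalize_tp10k_log(sim$counts)
  cl <- sim$truth$clone[sim$counts$cells]
  ratio <- mean(norm$tp10k[seg, cl == "cloneB"]) /
    mean(norm$tp10k[seg, cl == "cloneA"])
  expect_lt(abs(ratio - 2) / 2, 0.1)
})

test_that("identical clone profiles give no between-clone segment signal", {
  germ <- data.frame(chromosome = character(), start = integer(),
                     end = integer(), copy = numeric())
  clones <- list(list(clone_id = "cloneA", segments = germ),
                 list(clone_id = "cloneB", segments = germ))
  cfg <- tiny_sim_config(clones = clones,
                         ifn_effect = matrix(1, 2, 3))
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$truth$copy_number == 2))
  norm <- normalize_tp10k_log(sim$counts)
  cl <- sim$truth$clone[sim$counts$cells]
  a <- colMeans(t(norm$tp10k[, which(cl == "cloneA")]))
  b <- colMeans(t(norm$tp10k[, which(cl == "cloneB")]))
  # per-gene means agree up to sampling error; correlation of the difference
  # with chromosome position carries no structure
  expect_gt(cor(a, b), 0.95)
  expect_lt(abs(mean(a - b)), 0.05 * mean(a))
})

test_that("cfDNA mixture model and its hand-computed values", {
  germ <- data.frame(chromosome = character(), start = integer(),
                     end = integer(), copy = numeric())
  clones <- list(list(clone_id = "cloneA", segments = germ))
  cfg <- sim_config(n_genes = 300L, n_chromosomes = 3L, n_immune_cells = 0L,
                    n_malignant_cells = 10L, time_points = 0L,
                    clone_fractions = matrix(1, 1, 1), clones = clones,
                    ifn_effect = matrix(1, 1, 1), immune_ifn_effect = 1,
                    n_ifn_genes = 10L, n_antigen_genes = 8L,
                    n_marker_genes = 4L, n_housekeeping_genes = 8L,
                    cfdna_purity = 1, seed = 3)
  sim <- simulate_cohort(cfg)
  # purity 1, no noise, all-diploid single clone: observed tCR is 1 everywhere
  prof <- simulate_cfdna(sim$truth, 1, purity = 1, noise_sd = 0)
  expect_true(all(prof$tcr == 1))

  # a copy-4 gene at purity 0.5: 0.5*2 + 0.5*1 = 1.5
  clones4 <- list(list(clone_id = "cloneA",
                       segments = data.frame(chromosome = "chr1", start = 1L,
                                             end = 10L, copy = 4)))
  cfg4 <- sim_config(n_genes = 300L, n_chromosomes = 3L, n_immune_cells = 0L,
                     n_malignant_cells = 10L, time_points = 0L,
                     clone_fractions = matrix(1, 1, 1), clones = clones4,
                     ifn_effect = matrix(1, 1, 1), immune_ifn_effect = 1,
                     n_ifn_genes = 10L, n_antigen_genes = 8L,
                     n_marker_genes = 4L, n_housekeeping_genes = 8L,
                     cfdna_purity = 0.5, seed = 3)
  sim4 <- simulate_cohort(cfg4)
  prof4 <- simulate_cfdna(sim4$truth, 1, purity = 0.5, noise_sd = 0)
  amp <- sim4$annotation$symbol[sim4$annotation$chromosome == "chr1" &
                                  sim4$annotation$order_index <= 10]
  expect_equal(unname(prof4$tcr[amp]), rep(1.5, 10))
  expect_true(all(prof4$tcr[setdiff(names(prof4$tcr), amp)] == 1))
})

test_that("purity correction inverts the noise-free mixture exactly", {
  sim <- simulate_cohort(tiny_sim_config())
  for (p in c(0.2, 0.5, 0.9)) {
    prof <- simulate_cfdna(sim$truth, 2, purity = p, noise_sd = 0)
    corr <- purity_correct_tcr(prof)
    expect_equal(corr$tcr, sim$truth$true_tcr[[2]], tolerance = 1e-12)
  }
})
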