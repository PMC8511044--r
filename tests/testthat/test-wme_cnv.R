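toy_annotation <- function(n = 10, chr = "chr1", ig = rep(FALSE, n),
                           hla = rep(FALSE, n)) {
  gene_annotation(sprintf("g%02d", seq_len(n)), chr, seq_len(n), ig, hla)
}

test_that("CNV gene selection drops the top dropout decile and IG genes", {
  # gene i detected in i of 10 cells: 10 distinct dropout rates
  m <- matrix(0L, 10, 10, dimnames = list(sprintf("g%02d", 1:10),
                                          sprintf("c%02d", 1:10)))
  for (i in 1:10) m[i, seq_len(i)] <- 1L
  ann <- toy_annotation(10)
  kept <- select_cnv_genes(count_matrix(m), ann, dropout_quantile = 0.9)
  expect_identical(setdiff(ann$symbol, kept), "g01")  # highest dropout only

  # an always-detected, unflagged gene is retained
  expect_true("g10" %in% kept)

  # immunoglobulin flag removes a gene regardless of dropout
  ann_ig <- toy_annotation(10, ig = c(rep(FALSE, 9), TRUE))
  kept_ig <- select_cnv_genes(count_matrix(m), ann_ig, 0.9)
  expect_false("g10" %in% kept_ig)

  ann_all_ig <- toy_annotation(10, ig = rep(TRUE, 10))
  expect_warning(out <- select_cnv_genes(count_matrix(m), ann_all_ig, 0.9),
                 "no genes")
  expect_length(out, 0L)
})

test_that("window construction enumerates runs of consecutive eligible genes", {
  ann <- gene_annotation(sprintf("g%02d", 1:7),
                         c(rep("chr1", 5), rep("chr2", 2)),
                         c(1:5, 1:2))
  ws <- build_windows(ann, ann$symbol, window_size = 3, stride = 1)
  expect_length(ws$windows, 3L)
  expect_equal(lapply(ws$windows, `[[`, "genes"),
               list(c("g01", "g02", "g03"), c("g02", "g03", "g04"),
                    c("g03", "g04", "g05")))
  expect_true(all(vapply(ws$windows, `[[`, "", "chromosome") == "chr1"))

  tiling <- build_windows(ann, ann$symbol, window_size = 2, stride = 2)
  got <- unlist(lapply(tiling$windows, `[[`, "genes"))
  expect_false(anyDuplicated(got) > 0)  # stride = size partitions

  expect_error(build_windows(ann, ann$symbol, window_size = 0), "window_size")
})

test_that("uWME is a top-k-trimmed mean per cell and window", {
  tp10k <- named_matrix(c(10, 9, 8, 7, 6, 5, 4, 3), 8, 1)
  ann <- toy_annotation(8)
  ws <- build_windows(ann, rownames(tp10k), window_size = 8)
  u <- compute_uwme(make_norm(tp10k), ws, n_top_exclude = 5)
  expect_equal(unname(u[1, 1]), mean(c(5, 4, 3)))

  zero <- named_matrix(rep(0, 8), 8, 1)
  expect_equal(unname(compute_uwme(make_norm(zero), ws, 5)[1, 1]), 0)

  const <- named_matrix(rep(2.5, 8), 8, 1)
  expect_equal(unname(compute_uwme(make_norm(const), ws, 5)[1, 1]), 2.5)

  expect_error(compute_uwme(make_norm(tp10k),
                            build_windows(ann, rownames(tp10k), 4), 5),
               "n_top_exclude")
})

test_that("reference is a patient-level two-stage mean with HLA imputation", {
  ann <- toy_annotation(3)
  ws <- build_windows(ann, ann$symbol, window_size = 1)
  # patient A: 1 cell; patient B: 3 cells -- equal patient weight regardless
  uA <- named_matrix(rep(1, 3), 3, 1)
  uB <- named_matrix(rep(3, 3), 3, 3)
  ref <- build_reference(list(A = uA, B = uB), ws, ann)
  expect_equal(as.numeric(ref), rep(2, 3))

  # HLA-flagged window imputed with the mean of the non-HLA windows
  ann_hla <- toy_annotation(4, hla = c(FALSE, TRUE, FALSE, FALSE))
  ws4 <- build_windows(ann_hla, ann_hla$symbol, window_size = 1)
  u <- named_matrix(c(1, 99, 2, 3), 4, 1)
  ref4 <- build_reference(list(A = u), ws4, ann_hla)
  expect_equal(unname(ref4[2]), mean(c(1, 2, 3)))
  expect_true(attr(ref4, "imputed")[2])

  # zero reference windows are imputed too
  u0 <- named_matrix(c(1, 2, 0, 3), 4, 1)
  ref0 <- build_reference(list(A = u0), ws4, toy_annotation(4))
  expect_equal(unname(ref0[3]), mean(c(1, 2, 0, 3)))

  expect_error(build_reference(list(), ws, ann), "non-malignant")
})

test_that("WME normalization and rank transform behave as stated", {
  u <- named_matrix(c(1, 2, 3, 2, 4, 6), 3, 2)
  ref <- c(1, 2, 3)
  expect_equal(unname(normalize_wme(u, ref)[, 1]), rep(1, 3))
  expect_equal(normalize_wme(2 * u, ref), 2 * normalize_wme(u, ref))
  expect_error(normalize_wme(u, c(1, 0, 3)), "reference")

  wme <- named_matrix(c(0.5, 2.0, 1.0), 3, 1)
  expect_equal(unname(rank_wme(wme)[, 1]), c(1, 3, 2))
  const <- named_matrix(rep(1, 5), 5, 1)
  expect_equal(unname(rank_wme(const)[, 1]), rep(3, 5))
  # rank invariance under strictly monotone transforms
  expect_equal(rank_wme(exp(wme)), rank_wme(wme))
})

test_that("full stack equals the brute-force oracle on a toy", {
  set.seed(42)
  n_genes <- 30; n_cells <- 6
  genes <- sprintf("g%02d", 1:n_genes)
  cells <- sprintf("c%02d", 1:n_cells)
  ann <- gene_annotation(genes, rep(c("chrA", "chrB"), each = 15),
                         rep(1:15, 2),
                         is_hla_6p = c(rep(FALSE, 20), TRUE, TRUE,
                                       rep(FALSE, 8)))
  tp10k <- matrix(round(rlnorm(n_genes * n_cells, 3, 1)), n_genes, n_cells,
                  dimnames = list(genes, cells))
  tp10k[5, ] <- tp10k[6, ]  # inject ties to exercise average ranks
  malignant <- cells[1:3]
  nonmal <- list(P1 = cells[4:5], P2 = cells[6])

  ws <- build_windows(ann, genes, window_size = 8, stride = 1)
  norm <- make_norm(tp10k)
  uwme <- compute_uwme(norm, ws, n_top_exclude = 5)
  ref <- build_reference(lapply(nonmal, function(cl) uwme[, cl, drop = FALSE]),
                         ws, ann)
  wme <- normalize_wme(uwme[, malignant], ref)
  rwme <- rank_wme(wme)

  oracle <- brute_wme_stack(tp10k, ann, genes, window_size = 8, n_top = 5,
                            malignant_cells = malignant,
                            nonmalignant_by_patient = nonmal)
  expect_equal(length(ws$windows), length(oracle$windows))
  expect_equal(unname(uwme[, malignant]), unname(oracle$uwme))
  expect_equal(as.numeric(ref), unname(oracle$reference))
  expect_equal(unname(wme), unname(oracle$wme))
  expect_equal(unname(rwme), unname(oracle$rwme))
})

test_that("rWME is invariant to per-cell library scaling before TP10k", {
  sim <- simulate_cohort(tiny_sim_config(seed = 5))
  counts <- as.matrix(sim$counts$counts)
  # powers of two keep the TP10k division bit-identical
  scaled <- counts %*% diag(rep(c(1L, 4L), length.out = ncol(counts)))
  dimnames(scaled) <- dimnames(counts)
  st1 <- compute_wme_stack(count_matrix(counts), sim$annotation, sim$metadata,
                           window_size = 30, uwme_min_complexity = 100)
  st2 <- compute_wme_stack(count_matrix(scaled), sim$annotation, sim$metadata,
                           window_size = 30, uwme_min_complexity = 100)
  expect_equal(st1$rwme, st2$rwme)
})
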