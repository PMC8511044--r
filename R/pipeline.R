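#' Run the full pipeline and write per-stage artifacts
#'
#' Executes the stages in order — simulate (or load), preprocess, windowed
#' CNV inference, subclone discovery, cfDNA concordance, signature scoring,
#' statistics — writing TSV/JSON artifacts for each stage under `outdir`,
#' plus a manifest recording the seed, package version and config hash.
#' Given the same config (including seed) and inputs, reruns are
#' byte-identical.
#'
#' @param config A [pipeline_config()]; `config$sim` holds [sim_config()]
#'   overrides used when no inputs are given.
#' @param input_paths Optional list with `counts`, `annotation`, `metadata`
#'   (and optionally `copy_ratios`, `gene_sets`) paths; when `NULL` a
#'   synthetic cohort is generated from `config$sim`.
#' @param outdir Output directory (created if needed).
#' @param log_level `"debug"`, `"info"` or `"warn"`.
#' @return Invisibly, a list with the stage results and `outdir`.
#' @export
run_pipeline <- function(config = pipeline_config(), input_paths = NULL,
                         outdir, log_level = "info") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  .log_env$level <- log_level
  .log_env$file <- file.path(outdir, "run.log")
  on.exit({ .log_env$file <- NULL }, add = TRUE)

  stage <- function(name, fun) {
    pipeline_log("info", paste("stage:", name))
    tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # -- inputs -----------------------------------------------------------
  sim_truth <- NULL
  dat <- stage("input", function() {
    if (is.null(input_paths)) {
      sc <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
      sim <- simulate_cohort(sc)
      sim_truth <<- sim$truth
      write_table_tsv(sim$metadata, file.path(outdir, "metadata.tsv"))
      sim
    } else {
      load_dataset(input_paths$counts, input_paths$annotation,
                   input_paths$metadata)
    }
  })

  # -- preprocess -------------------------------------------------------
  pp <- stage("preprocess", function() {
    hk <- if (!is.null(sim_truth)) sim_truth$signatures$housekeeping
          else load_gene_sets(input_paths$gene_sets)[["housekeeping"]]
    fb <- filter_barcodes(dat$counts, hk, config$complexity_cutoff,
                          config$hk_cutoff)
    utils::write.table(fb$qc, file.path(outdir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    general <- filter_genes(fb$counts, config$gene_min_fraction)
    wme_input <- filter_genes(fb$counts, config$wme_gene_min_fraction)
    list(qc = fb$qc, general = general, wme_input = wme_input)
  })

  # -- windowed CNV -----------------------------------------------------
  stack <- stage("wme_cnv", function() {
    st <- compute_wme_stack(pp$wme_input, dat$annotation, dat$metadata,
                            window_size = config$window_size,
                            stride = config$window_stride,
                            n_top_exclude = config$n_top_exclude,
                            dropout_quantile = config$dropout_quantile,
                            uwme_min_complexity = config$uwme_min_complexity)
    write_windows(st$window_set, file.path(outdir, "windows.tsv"))
    write_matrix_tsv(st$wme, file.path(outdir, "wme.tsv"))
    write_matrix_tsv(st$rwme, file.path(outdir, "rwme.tsv"))
    st
  })

  # -- subclones --------------------------------------------------------
  sub <- stage("subclone", function() {
    d <- kendall_distance_matrix(stack$wme)
    asg <- cluster_wpgma(d, k = config$n_clusters)
    asg <- label_clones(asg, dat$metadata)
    fr <- asg$fractions
    utils::write.table(
      data.frame(barcode = asg$cells, cluster = asg$cluster),
      file.path(outdir, "subclone_assignment.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fr, file.path(outdir, "clone_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_dendrogram(asg, file.path(outdir, "dendrogram.nwk"))
    list(assignment = asg, fractions = fr)
  })

  # -- cfDNA concordance ------------------------------------------------
  conc <- stage("cfdna_concordance", function() {
    profiles <- if (!is.null(sim_truth)) {
      n_tp <- length(sim_truth$time_points)
      lapply(seq_len(n_tp), function(t)
        simulate_cfdna(sim_truth, t, sim_truth$config$cfdna_purity[t],
                       sim_truth$config$cfdna_noise_sd,
                       seed = config$seed + t))
    } else if (!is.null(input_paths$copy_ratios)) {
      load_copy_ratios(input_paths$copy_ratios)
    } else return(NULL)
    if (length(profiles) < 2) return(NULL)
    corrected <- lapply(profiles, purity_correct_tcr)
    norm <- normalize_tp10k_log(
      count_matrix(pp$general$counts[, stack$cells, drop = FALSE]))
    shift <- correlation_shift(norm, corrected[[1]],
                               corrected[[length(corrected)]], dat$metadata)
    utils::write.table(shift$table, file.path(outdir, "concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(summary = shift$summary),
      file.path(outdir, "concordance_summary.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
    list(profiles = profiles, corrected = corrected, shift = shift)
  })

  # -- signatures -------------------------------------------------------
  scores <- stage("signatures", function() {
    sets <- if (!is.null(sim_truth))
      gene_set_collection(list(
        ifn_response = sim_truth$signatures$ifn_response,
        antigen_presentation = sim_truth$signatures$antigen_presentation))
    else load_gene_sets(input_paths$gene_sets)
    if (all(c("ifn_response", "antigen_presentation") %in% names(sets)))
      sets <- sanitize_gene_sets(sets, c("ifn_response", "antigen_presentation"))
    norm <- normalize_tp10k_log(pp$general)
    out <- lapply(names(sets), function(nm)
      module_score(norm, sets[[nm]], n_bins = config$n_bins,
                   n_ctrl = config$n_ctrl, seed = config$seed))
    names(out) <- names(sets)
    tab <- Reduce(function(a, b) merge(a, b, by = "barcode"),
                  Map(function(s, nm) stats::setNames(s, c("barcode", nm)),
                      out, names(out)))
    utils::write.table(tab, file.path(outdir, "module_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out
  })

  # -- statistics -------------------------------------------------------
  stats_out <- stage("stats_report", function() {
    ifn <- scores$ifn_response
    tumor <- dat$metadata$barcode[dat$metadata$is_malignant]
    res <- list(
      tumor_ifn = sample_group_compare(
        ifn[ifn$barcode %in% tumor, ], dat$metadata,
        min_cells = config$min_cells_module,
        boundary = config$phase_boundary_days),
      immune_ifn = sample_group_compare(
        ifn[!ifn$barcode %in% tumor, ], dat$metadata,
        min_cells = config$min_cells_module,
        boundary = config$phase_boundary_days))
    tab <- do.call(rbind, Map(cbind, comparison = names(res), res))
    tab$p_adjusted <- bonferroni_adjust(
      ifelse(is.na(tab$p_value), 0, tab$p_value))
    tab$p_adjusted[is.na(tab$p_value)] <- NA
    utils::write.table(tab, file.path(outdir, "comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tab
  })

  manifest <- list(package = "wmeclone",
                   version = as.character(utils::packageVersion("wmeclone")),
                   seed = config$seed,
                   config_hash = config_hash(config),
                   stages = c("input", "preprocess", "wme_cnv", "subclone",
                              "cfdna_concordance", "signatures", "stats_report"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_config(config, file.path(outdir, "config.yaml"))
  invisible(list(data = dat, preprocess = pp, stack = stack, subclone = sub,
                 concordance = conc, scores = scores, stats = stats_out,
                 outdir = outdir))
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(row = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
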