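#' Load a counts + annotation + metadata dataset
#'
#' Reads a UMI count matrix (MatrixMarket triplet with gene/barcode sidecar
#' lists, or dense TSV with gene symbols in the first column and barcodes as
#' header), a gene annotation table and a cell metadata table, and
#' cross-validates them. Genes absent from the annotation are retained but
#' flagged un-annotated (attribute `unannotated` on the returned annotation).
#'
#' @param counts_path Path to `.mtx` (sidecars `<stem>.genes.tsv`,
#'   `<stem>.barcodes.tsv` beside it) or dense `.tsv`.
#' @param annotation_path TSV with columns `symbol`, `chromosome`,
#'   `order_index`, `is_immunoglobulin`, `is_hla_6p`.
#' @param metadata_path TSV with columns `barcode`, `sample_id`, `patient_id`,
#'   `compartment`, `days_since_first_dose`, `cell_type`, `is_malignant`.
#' @return List with elements `counts` (`count_matrix`), `annotation`
#'   (`gene_annotation`) and `metadata` (`cell_metadata`).
#' @export
load_dataset <- function(counts_path, annotation_path, metadata_path) {
  cm <- read_counts(counts_path)
  ann <- read_annotation(annotation_path)
  md <- read_metadata(metadata_path)
  if (!all(md$barcode %in% cm$cells))
    stop("integrity error: metadata barcodes missing from count matrix: ",
         paste(utils::head(setdiff(md$barcode, cm$cells), 5), collapse = ", "),
         call. = FALSE)
  unann <- setdiff(cm$genes, ann$symbol)
  if (length(unann))
    pipeline_log("info", sprintf("%d genes in counts lack annotation; retained un-annotated",
                                 length(unann)))
  attr(ann, "unannotated") <- unann
  list(counts = cm, annotation = ann, metadata = md)
}

read_counts <- function(path) {
  if (grepl("\\.mtx$", path)) {
    stem <- sub("\\.mtx$", "", path)
    genes <- readLines(paste0(stem, ".genes.tsv"))
    cells <- readLines(paste0(stem, ".barcodes.tsv"))
    m <- Matrix::readMM(path)
    count_matrix(m, genes = genes, cells = cells)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    count_matrix(m)
  }
}

#' Write a count matrix
#'
#' @param cm A `count_matrix`.
#' @param path Output path; `.mtx` writes MatrixMarket triplet plus
#'   `<stem>.genes.tsv` / `<stem>.barcodes.tsv` sidecars, anything else a
#'   dense TSV with a leading `gene` column.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  if (grepl("\\.mtx$", path)) {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(cm$counts, path)
    writeLines(cm$genes, paste0(stem, ".genes.tsv"))
    writeLines(cm$cells, paste0(stem, ".barcodes.tsv"))
  } else {
    df <- data.frame(gene = cm$genes, as.matrix(cm$counts), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

required_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("format error: %s lacks required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required_columns(df, c("symbol", "chromosome", "order_index",
                         "is_immunoglobulin", "is_hla_6p"), "annotation")
  gene_annotation(df$symbol, df$chromosome, df$order_index,
                  as.logical(df$is_immunoglobulin), as.logical(df$is_hla_6p))
}

read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required_columns(df, c("barcode", "sample_id", "patient_id", "compartment",
                         "days_since_first_dose", "cell_type", "is_malignant"),
                   "metadata")
  cell_metadata(df$barcode, df$sample_id, df$patient_id, df$compartment,
                df$days_since_first_dose, df$cell_type, as.logical(df$is_malignant))
}

#' Write annotation / metadata tables
#'
#' @param x A `gene_annotation` or `cell_metadata`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene symbols. Duplicate genes within a set are collapsed.
#'
#' @param gmt_path Path to a GMT file.
#' @return A `gene_set_collection`.
#' @export
load_gene_sets <- function(gmt_path) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop(sprintf("format error: GMT line %d has no genes", bad[1]), call. = FALSE)
  nm <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(nm))
    stop("integrity error: duplicate gene set names in GMT", call. = FALSE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- nm
  gene_set_collection(sets)
}

#' Write gene sets to a GMT file
#'
#' @param sets A `gene_set_collection` or named list of gene vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Load cfDNA gene-level total copy ratios
#'
#' TSV with columns `sample_id`, `purity`, `gene`, `tcr`; one
#' `copy_ratio_profile` is returned per sample.
#'
#' @param path TSV path.
#' @return Named list of `copy_ratio_profile`, one per `sample_id`.
#' @export
load_copy_ratios <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required_columns(df, c("sample_id", "purity", "gene", "tcr"), "copy ratio table")
  out <- lapply(split(df, df$sample_id), function(d) {
    if (length(unique(d$purity)) != 1)
      stop("integrity error: inconsistent purity within sample ", d$sample_id[1],
           call. = FALSE)
    copy_ratio_profile(d$sample_id[1], d$purity[1],
                       stats::setNames(d$tcr, d$gene))
  })
  out[order(names(out))]
}

#' Write copy-ratio profiles
#'
#' @param profiles A `copy_ratio_profile` or list of them.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_copy_ratios <- function(profiles, path) {
  if (inherits(profiles, "copy_ratio_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(sample_id = p$sample_id, purity = p$purity,
               gene = names(p$tcr), tcr = unname(p$tcr))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# lightweight leveled logger; level set per run_pipeline call
.log_env <- new.env(parent = emptyenv())
.log_env$level <- "info"
.log_env$file <- NULL

pipeline_log <- function(level = c("info", "warn", "debug"), msg) {
  level <- match.arg(level)
  ranks <- c(debug = 1, info = 2, warn = 3)
  line <- sprintf("[%s] %s", toupper(level), msg)
  if (!is.null(.log_env$file)) cat(line, "\n", file = .log_env$file, append = TRUE)
  if (ranks[[level]] >= ranks[[.log_env$level]]) message(line)
  invisible(line)
}
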