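#' Construct a validated UMI count matrix
#'
#' The raw substrate of every pipeline stage: a genes x cells matrix of
#' non-negative integer UMI counts with unique gene symbols and barcodes.
#'
#' @param counts Numeric matrix (base or `Matrix` sparse), genes in rows,
#'   cells in columns. Values must be non-negative integers.
#' @param genes Character vector of gene symbols (defaults to rownames).
#' @param cells Character vector of cell barcodes (defaults to colnames).
#' @return An object of class `count_matrix`: a list with elements `genes`,
#'   `cells` and `counts` (a `dgCMatrix` carrying the same dimnames).
#' @export
count_matrix <- function(counts, genes = rownames(counts), cells = colnames(counts)) {
  if (is.null(genes) || is.null(cells))
    stop("count_matrix requires gene and cell identifiers", call. = FALSE)
  if (anyDuplicated(genes))
    stop("integrity error: duplicate gene symbols in count matrix", call. = FALSE)
  if (anyDuplicated(cells))
    stop("integrity error: duplicate cell barcodes in count matrix", call. = FALSE)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != round(v))))
    stop("counts must be non-negative integers", call. = FALSE)
  dimnames(counts) <- list(genes, cells)
  structure(list(genes = genes, cells = cells, counts = counts),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells, %d nonzero entries\n",
              length(x$genes), length(x$cells), length(x$counts@x)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Construct a validated gene annotation table
#'
#' Carries the genomic ordering that window construction relies on: genes are
#' located only by a 1-based rank within their chromosome, not by base-pair
#' coordinates, since windows need order alone. Flags mark immunoglobulin
#' genes (excluded from CNV inference) and HLA/6p genes (whose reference
#' windows are imputed).
#'
#' @param symbol,chromosome Character vectors.
#' @param order_index Integer rank of each gene within its chromosome,
#'   contiguous from 1.
#' @param is_immunoglobulin,is_hla_6p Logical flags.
#' @return A `data.frame` of class `gene_annotation`.
#' @export
gene_annotation <- function(symbol, chromosome, order_index,
                            is_immunoglobulin = FALSE, is_hla_6p = FALSE) {
  df <- data.frame(symbol = as.character(symbol),
                   chromosome = as.character(chromosome),
                   order_index = as.integer(order_index),
                   is_immunoglobulin = rep_len(as.logical(is_immunoglobulin), length(symbol)),
                   is_hla_6p = rep_len(as.logical(is_hla_6p), length(symbol)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$symbol))
    stop("integrity error: duplicate gene symbols in annotation", call. = FALSE)
  if (anyDuplicated(df[c("chromosome", "order_index")]))
    stop("integrity error: duplicate (chromosome, order_index) in annotation", call. = FALSE)
  for (chr in unique(df$chromosome)) {
    oi <- sort(df$order_index[df$chromosome == chr])
    if (!identical(oi, seq_along(oi)))
      stop(sprintf("order_index not contiguous from 1 on %s", chr), call. = FALSE)
  }
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Construct a validated cell metadata table
#'
#' One row per barcode: sample, patient, compartment (CSF or PBL), days since
#' the first checkpoint-inhibitor dose (<= 0 means pre-treatment), cell-type
#' label and malignancy flag.
#'
#' @param barcode,sample_id,patient_id,compartment,cell_type Character vectors.
#' @param days_since_first_dose Integer vector; negative or zero = pre-treatment.
#' @param is_malignant Logical vector.
#' @return A `data.frame` of class `cell_metadata`.
#' @export
cell_metadata <- function(barcode, sample_id, patient_id, compartment,
                          days_since_first_dose, cell_type, is_malignant) {
  compartment <- as.character(compartment)
  if (!all(compartment %in% c("CSF", "PBL")))
    stop("compartment must be 'CSF' or 'PBL'", call. = FALSE)
  if (anyNA(days_since_first_dose))
    stop("format error: days_since_first_dose missing for some barcodes", call. = FALSE)
  df <- data.frame(barcode = as.character(barcode),
                   sample_id = as.character(sample_id),
                   patient_id = as.character(patient_id),
                   compartment = compartment,
                   days_since_first_dose = as.integer(days_since_first_dose),
                   cell_type = as.character(cell_type),
                   is_malignant = as.logical(is_malignant),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$barcode))
    stop("integrity error: duplicate barcodes in metadata", call. = FALSE)
  class(df) <- c("cell_metadata", "data.frame")
  df
}

#' Construct a gene set collection
#'
#' @param sets Named list of character vectors of gene symbols. Duplicates
#'   within a set are collapsed; empty sets and duplicate names are errors.
#' @return Named list of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set must be named", call. = FALSE)
  if (anyDuplicated(names(sets)))
    stop("integrity error: duplicate gene set names", call. = FALSE)
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0))
    stop("format error: empty gene set", call. = FALSE)
  structure(sets, class = "gene_set_collection")
}

#' Construct a cfDNA copy-ratio profile
#'
#' Gene-level total copy ratios (tCR; germline reference = 1) from cfDNA
#' whole-exome sequencing, together with the sample's tumor purity.
#'
#' @param sample_id Sample identifier.
#' @param purity Tumor fraction in (0, 1].
#' @param tcr Named non-negative numeric vector, names = gene symbols.
#' @return Object of class `copy_ratio_profile`.
#' @export
copy_ratio_profile <- function(sample_id, purity, tcr) {
  if (!is.numeric(purity) || length(purity) != 1 || is.na(purity) ||
      purity <= 0 || purity > 1)
    stop("value error: purity must lie in (0, 1]", call. = FALSE)
  if (is.null(names(tcr)) || anyDuplicated(names(tcr)))
    stop("tcr must be a uniquely named vector", call. = FALSE)
  if (any(tcr < 0)) stop("value error: tcr must be non-negative", call. = FALSE)
  structure(list(sample_id = as.character(sample_id),
                 purity = as.numeric(purity),
                 tcr = tcr),
            class = "copy_ratio_profile")
}

#' Default pipeline configuration
#'
#' Every stage parameter with its default, plus the master random seed. A
#' serialized config and the same inputs reproduce a run bit-identically.
#'
#' @param ... Named overrides of any default listed below.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # barcode QC
    complexity_cutoff = 400L,
    pbl_complexity_cutoff = 200L,
    hk_cutoff = 1.6,
    # gene retention
    gene_min_fraction = 0.01,
    wme_gene_min_fraction = 0.000875,
    # windowed mean expression
    window_size = 200L,
    window_stride = 1L,
    n_top_exclude = 5L,
    dropout_quantile = 0.9,
    uwme_min_complexity = 1000L,
    # subclone discovery
    n_clusters = 4L,
    n_pcs = 50L,
    # module scoring
    n_bins = 25L,
    n_ctrl = 100L,
    # statistics
    phase_boundary_days = 30L,
    min_cells_tcell = 20L,
    min_cells_cd8 = 10L,
    min_cells_module = 5L,
    downsample_target_umis = 500L,
    # simulation defaults live in sim_config()
    sim = list()
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Serialize / restore a pipeline configuration
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` the config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(unclass(config)), tf)
  unname(tools::md5sum(tf))
}
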