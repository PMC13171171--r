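#' Quantification bundle
#'
#' In-memory container for a UMI quantification result: a sparse
#' barcodes-by-genes count matrix, optional spliced/unspliced/ambiguous
#' (S/U/A) layers from splice-aware quantification, the barcode and gene
#' identifier lists, and parsed log metadata.
#'
#' Invariants enforced by the constructor: all matrices share dimensions
#' matching the barcode/gene lists, counts are non-negative, and when the
#' three layers are present the total layer equals their elementwise sum.
#'
#' @param counts sparse (or dense) barcodes-by-genes matrix of total UMI
#'   counts. If `NULL` and layers are supplied it is rebuilt as S + U + A.
#' @param barcodes character vector of barcode identifiers (rows).
#' @param genes character vector of gene identifiers (columns).
#' @param layer_S,layer_U,layer_A optional matrices of spliced, unspliced
#'   and ambiguous UMI counts, same shape as `counts`.
#' @param gene_symbols optional character vector of gene symbols, parallel
#'   to `genes` (used e.g. for mitochondrial gene detection).
#' @param log_meta a [log_summary()] object, or `NULL`.
#' @return an object of class `quant_bundle`.
#' @export
quant_bundle <- function(counts = NULL, barcodes, genes,
                         layer_S = NULL, layer_U = NULL, layer_A = NULL,
                         gene_symbols = NULL, log_meta = NULL) {
  has_layers <- !is.null(layer_S) || !is.null(layer_U) || !is.null(layer_A)
  if (has_layers) {
    if (is.null(layer_S) || is.null(layer_U) || is.null(layer_A))
      stopf("either all of S/U/A layers must be given, or none")
    layer_S <- as_dgc(layer_S); layer_U <- as_dgc(layer_U); layer_A <- as_dgc(layer_A)
    if (is.null(counts)) counts <- layer_S + layer_U + layer_A
  }
  if (is.null(counts)) stopf("counts missing and no layers to rebuild it from")
  counts <- as_dgc(counts)

  barcodes <- as.character(barcodes); genes <- as.character(genes)
  if (nrow(counts) != length(barcodes))
    stopf("matrix has %d rows but %d barcodes", nrow(counts), length(barcodes))
  if (ncol(counts) != length(genes))
    stopf("matrix has %d columns but %d genes", ncol(counts), length(genes))
  if (any(counts@x < 0)) stopf("negative counts are not allowed")
  if (has_layers) {
    for (nm in c("layer_S", "layer_U", "layer_A")) {
      l <- get(nm)
      if (!identical(dim(l), dim(counts)))
        stopf("%s dimensions do not match counts", nm)
      if (any(l@x < 0)) stopf("negative counts in %s", nm)
    }
    if (max(abs((layer_S + layer_U + layer_A) - counts)) > 0)
      stopf("counts != S + U + A")
  }
  if (!is.null(gene_symbols) && length(gene_symbols) != length(genes))
    stopf("gene_symbols length does not match genes")
  if (is.null(log_meta)) log_meta <- log_summary()

  structure(list(
    counts = counts,
    layer_S = if (has_layers) layer_S else NULL,
    layer_U = if (has_layers) layer_U else NULL,
    layer_A = if (has_layers) layer_A else NULL,
    barcodes = barcodes, genes = genes, gene_symbols = gene_symbols,
    log_meta = log_meta
  ), class = "quant_bundle")
}

#' @export
print.quant_bundle <- function(x, ...) {
  cat(sprintf("quant_bundle: %d barcodes x %d genes, %s UMIs total\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  cat(sprintf("  S/U/A layers: %s\n", if (has_usa_layers(x)) "present" else "absent"))
  cat(sprintf("  logs: %s\n",
              if (length(x$log_meta$raw_log_tables)) "parsed" else "absent"))
  invisible(x)
}

#' @export
dim.quant_bundle <- function(x) dim(x$counts)

#' Does the bundle carry splice-aware S/U/A layers?
#' @param bundle a [quant_bundle()].
#' @return logical scalar.
#' @export
has_usa_layers <- function(bundle) !is.null(bundle$layer_S)

#' Per-barcode total UMI counts
#' @param bundle a [quant_bundle()].
#' @return numeric vector, one total per barcode, in barcode-file order.
#' @export
barcode_totals <- function(bundle) {
  unname(Matrix::rowSums(bundle$counts))
}

#' Log metadata container
#'
#' Holds fields recognized from the quantification-step and
#' permit-list-step JSON logs, plus every raw key/value table verbatim for
#' the report. Missing fields are `NA`, never zero.
#'
#' @param num_processed_reads,num_mapped_reads,num_processed_barcodes
#'   scalar counts or `NA`.
#' @param chemistry chemistry tag string or `NA`.
#' @param tool_versions,command_arguments named character vectors.
#' @param raw_log_tables named list (one element per log file) of named
#'   key/value lists, order preserved.
#' @return an object of class `log_summary`.
#' @export
log_summary <- function(num_processed_reads = NA_real_,
                        num_mapped_reads = NA_real_,
                        num_processed_barcodes = NA_real_,
                        chemistry = NA_character_,
                        tool_versions = character(),
                        command_arguments = character(),
                        raw_log_tables = list()) {
  if (!is.na(num_processed_reads) && !is.na(num_mapped_reads) &&
      num_mapped_reads > num_processed_reads) {
    warnf("log reports more mapped (%s) than processed (%s) reads",
          format(num_mapped_reads), format(num_processed_reads))
  }
  structure(list(
    num_processed_reads = as.numeric(num_processed_reads),
    num_mapped_reads = as.numeric(num_mapped_reads),
    num_processed_barcodes = as.numeric(num_processed_barcodes),
    chemistry = as.character(chemistry),
    tool_versions = tool_versions,
    command_arguments = command_arguments,
    raw_log_tables = raw_log_tables
  ), class = "log_summary")
}
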