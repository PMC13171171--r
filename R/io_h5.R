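# Annotated-matrix HDF5 (H5AD-compatible) input/output. No R HDF5 binding
# is assumed: a bundled python helper backed by the anndata library does
# the container work; data crosses the boundary through a plain-text
# exchange directory (MTX + TSV + JSON), written at full precision so
# numeric columns round-trip exactly.

FLAG_COLUMNS <- c("ordmag_retained", "retained", "is_doublet")

write_exchange_dir <- function(bundle, obs, uns, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(bundle$counts, file.path(dir, "X.mtx"))
  if (has_usa_layers(bundle)) {
    Matrix::writeMM(bundle$layer_S, file.path(dir, "S.mtx"))
    Matrix::writeMM(bundle$layer_U, file.path(dir, "U.mtx"))
    Matrix::writeMM(bundle$layer_A, file.path(dir, "A.mtx"))
  }
  writeLines(bundle$barcodes, file.path(dir, "barcodes.tsv"))
  gl <- if (!is.null(bundle$gene_symbols))
    paste(bundle$genes, bundle$gene_symbols, sep = "\t") else bundle$genes
  writeLines(gl, file.path(dir, "genes.tsv"))
  if (!is.null(obs) && ncol(obs) > 0) {
    ser <- obs
    for (j in seq_along(ser)) {
      if (is.logical(ser[[j]])) ser[[j]] <- as.integer(ser[[j]])
      if (is.double(ser[[j]])) ser[[j]] <- fmt_full(ser[[j]])
    }
    utils::write.table(ser, file.path(dir, "obs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }
  jsonlite::write_json(uns, file.path(dir, "uns.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
}

read_exchange_dir <- function(dir) {
  counts <- read_mm(file.path(dir, "X.mtx"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  gl <- strsplit(readLines(file.path(dir, "genes.tsv")), "\t", fixed = TRUE)
  genes <- vapply(gl, `[[`, character(1), 1L)
  symbols <- if (all(lengths(gl) >= 2L)) vapply(gl, `[[`, character(1), 2L) else NULL
  layers <- list()
  for (l in c("S", "U", "A")) {
    f <- file.path(dir, paste0(l, ".mtx"))
    if (file.exists(f)) layers[[l]] <- read_mm(f)
  }
  obs <- NULL
  if (file.exists(file.path(dir, "obs.tsv"))) {
    obs <- utils::read.delim(file.path(dir, "obs.tsv"), sep = "\t",
                             stringsAsFactors = FALSE, na.strings = "NA")
    for (nm in names(obs)) {
      if (nm %in% FLAG_COLUMNS) obs[[nm]] <- obs[[nm]] > 0
      else if (is.logical(obs[[nm]])) obs[[nm]] <- as.numeric(obs[[nm]])  # all-NA
    }
  }
  uns <- if (file.exists(file.path(dir, "uns.json")))
    jsonlite::read_json(file.path(dir, "uns.json")) else list()
  list(counts = counts, barcodes = barcodes, genes = genes, symbols = symbols,
       layers = layers, obs = obs, uns = uns)
}

#' Export an annotated HDF5 matrix file
#'
#' Writes one H5AD-compatible file holding the count matrix (plus S/U/A
#' layers when present), per-barcode annotation columns (total UMIs, genes
#' detected, mitochondrial fraction, cell-calling outcome, doublet scores
#' when computed) and unstructured metadata (summary statistics, parsed
#' log tables, parameters). The mitochondrial fraction is stored for the
#' user's own filtering decisions; it is never used to filter here.
#'
#' @param bundle a [quant_bundle()].
#' @param calls a [call_cells()] result, or `NULL`.
#' @param qc a [summarize_qc()] result, or `NULL`.
#' @param doublets a [doublet_scores()] result, or `NULL`.
#' @param path output file path (`.h5ad`).
#' @param mito_genes optional explicit mitochondrial gene list, passed to
#'   [per_barcode_qc()].
#' @return `path`, invisibly.
#' @export
export_h5 <- function(bundle, calls = NULL, qc = NULL, doublets = NULL, path,
                      mito_genes = NULL) {
  obs <- per_barcode_qc(bundle, calls = calls, mito_genes = mito_genes)
  if (!is.null(doublets)) {
    score <- rep(NA_real_, nrow(bundle$counts))
    flag <- rep(NA, nrow(bundle$counts))
    score[doublets$cell_indices] <- doublets$observed_scores
    flag[doublets$cell_indices] <- doublets$is_doublet
    obs$doublet_score <- score
    obs$is_doublet <- flag
  }
  uns <- list(tool = "umiqc", tool_version = "0.1.0")
  if (!is.null(qc)) uns$qc_summary <- unclass(qc)
  if (!is.null(calls)) uns$cell_calling <- calls$parameters
  lm <- bundle$log_meta
  if (length(lm$raw_log_tables)) uns$log_tables <- lm$raw_log_tables
  uns$log_fields <- list(
    num_processed_reads = lm$num_processed_reads,
    num_mapped_reads = lm$num_mapped_reads,
    num_processed_barcodes = lm$num_processed_barcodes,
    chemistry = lm$chemistry)

  xdir <- tempfile("umiqc_x2h5_")
  on.exit(unlink(xdir, recursive = TRUE))
  write_exchange_dir(bundle, obs, uns, xdir)
  run_python(py_script("h5ad_bridge.py"), c("to_h5ad", xdir, path))
  if (!file.exists(path)) stopf("failed to write '%s'", path)
  invisible(path)
}

#' Load an annotated HDF5 matrix file
#'
#' Reads an H5AD-compatible file into a [quant_bundle()]. If S/U/A layers
#' are present but the total matrix is missing or inconsistent, the total
#' is rebuilt as S + U + A. Per-barcode annotation columns and
#' unstructured metadata, when present, are attached as `$obs` and `$uns`.
#'
#' @param path path to the `.h5ad` file.
#' @return a [quant_bundle()] with optional `$obs` / `$uns` attachments.
#' @export
load_h5_input <- function(path) {
  if (!file.exists(path)) stopf("file '%s' does not exist", path)
  xdir <- tempfile("umiqc_h52x_")
  on.exit(unlink(xdir, recursive = TRUE))
  run_python(py_script("h5ad_bridge.py"), c("from_h5ad", path, xdir))
  ex <- read_exchange_dir(xdir)

  counts <- ex$counts
  if (length(ex$layers) == 3L) {
    total <- ex$layers$S + ex$layers$U + ex$layers$A
    if (is.null(counts) || max(abs(counts - total)) > 0) counts <- total
    b <- quant_bundle(counts = counts, barcodes = ex$barcodes, genes = ex$genes,
                      layer_S = ex$layers$S, layer_U = ex$layers$U,
                      layer_A = ex$layers$A, gene_symbols = ex$symbols)
  } else {
    b <- quant_bundle(counts = counts, barcodes = ex$barcodes, genes = ex$genes,
                      gene_symbols = ex$symbols)
  }
  lf <- ex$uns$log_fields
  if (!is.null(lf)) {
    nn <- function(x) if (is.null(x)) NA else x
    b$log_meta <- log_summary(
      num_processed_reads = nn(lf$num_processed_reads),
      num_mapped_reads = nn(lf$num_mapped_reads),
      num_processed_barcodes = nn(lf$num_processed_barcodes),
      chemistry = nn(lf$chemistry),
      raw_log_tables = if (!is.null(ex$uns$log_tables)) ex$uns$log_tables else list())
  }
  b$obs <- ex$obs
  b$uns <- ex$uns
  b
}
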