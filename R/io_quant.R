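# Reading quantification directories: MatrixMarket counts + barcode and
# feature lists + JSON step logs. Splice-aware (USA-mode) outputs encode
# unspliced and ambiguous features as "<gene>-U" / "<gene>-A" alongside the
# unsuffixed spliced feature; the loader collapses the three blocks onto a
# single gene axis and keeps them as layers.

find_one <- function(dir, patterns, what, required = TRUE) {
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  for (p in patterns) {
    hit <- files[grepl(p, basename(files), ignore.case = TRUE)]
    if (length(hit)) return(hit[[1]])
  }
  if (required) stopf("no %s file found under '%s'", what, dir)
  NULL
}

read_lines_maybe_gz <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

read_mm <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt"); on.exit(close(con))
    as_dgc(Matrix::readMM(con))
  } else {
    as_dgc(Matrix::readMM(path))
  }
}

# USA auto-detection: >=1 feature ends in "-U" and stripping -U/-A suffixes
# collapses the feature set 3 -> 1.
detect_usa <- function(features) {
  if (!any(grepl("-U$", features))) return(FALSE)
  base <- sub("-(U|A)$", "", features)
  ub <- unique(base)
  length(ub) * 3L == length(features) &&
    all(ub %in% features) &&
    all(paste0(ub, "-U") %in% features) &&
    all(paste0(ub, "-A") %in% features)
}

#' Load a quantification output directory
#'
#' Locates the MatrixMarket count matrix plus barcode and feature lists
#' (and any JSON step logs) under `path` and assembles a [quant_bundle()].
#' When the features follow the splice-aware convention (spliced gene `g`
#' accompanied by `g-U` and `g-A` features), the three feature blocks are
#' collapsed onto one gene axis, stored as S/U/A layers, and the total
#' count matrix is their sum.
#'
#' @param path directory containing the quantification output.
#' @param usa_mode `"auto"` (default) detects the splice-aware feature
#'   convention; `TRUE`/`FALSE` force it.
#' @return a [quant_bundle()]. Barcode order follows the barcode file.
#' @export
load_quant_dir <- function(path, usa_mode = "auto") {
  if (!dir.exists(path)) stopf("directory '%s' does not exist", path)
  mtx_file <- find_one(path, c("\\.mtx(\\.gz)?$"), "MatrixMarket matrix")
  bc_file <- find_one(path, c("barcode", "quants_mat_rows"), "barcode list")
  ft_file <- find_one(path, c("feature", "genes", "quants_mat_cols"), "feature list")

  counts <- read_mm(mtx_file)
  barcodes <- read_lines_maybe_gz(bc_file)
  feat_lines <- read_lines_maybe_gz(ft_file)
  feat_tab <- strsplit(feat_lines, "\t", fixed = TRUE)
  features <- vapply(feat_tab, `[[`, character(1), 1L)
  symbols <- if (all(lengths(feat_tab) >= 2L))
    vapply(feat_tab, `[[`, character(1), 2L) else NULL

  if (nrow(counts) != length(barcodes))
    stopf("matrix '%s' has %d rows but barcode file '%s' has %d lines",
          basename(mtx_file), nrow(counts), basename(bc_file), length(barcodes))
  if (ncol(counts) != length(features))
    stopf("matrix '%s' has %d columns but feature file '%s' has %d lines",
          basename(mtx_file), ncol(counts), basename(ft_file), length(features))

  logs <- parse_logs(path)
  usa <- if (identical(usa_mode, "auto")) detect_usa(features) else isTRUE(usa_mode)
  if (usa && !detect_usa(features))
    stopf("usa_mode = TRUE but features do not follow the S/U/A suffix convention")

  if (!usa) {
    return(quant_bundle(counts = counts, barcodes = barcodes, genes = features,
                        gene_symbols = symbols, log_meta = logs))
  }

  spliced <- !grepl("-(U|A)$", features)
  genes <- features[spliced]
  sym <- if (!is.null(symbols)) symbols[spliced] else NULL
  idx <- function(suffix) match(paste0(genes, suffix), features)
  quant_bundle(
    barcodes = barcodes, genes = genes, gene_symbols = sym,
    layer_S = counts[, idx(""), drop = FALSE],
    layer_U = counts[, idx("-U"), drop = FALSE],
    layer_A = counts[, idx("-A"), drop = FALSE],
    log_meta = logs
  )
}

# tolerant key lookup across log-file dialects
log_pick <- function(tabs, keys) {
  for (tab in tabs) for (k in keys) {
    v <- tab[[k]]
    if (!is.null(v) && length(v) == 1L && !is.list(v)) return(v)
  }
  NULL
}

#' Parse quantification and permit-list step logs
#'
#' Scans `path` for the JSON log files written by the quantification and
#' permit-list steps (file names containing `quant` or `permit` and ending
#' in `.json`), extracts the recognized fields, and preserves every raw
#' key/value pair for the report's log tables. Absent or malformed logs
#' degrade to absent fields with a warning, never an error.
#'
#' @param path directory to scan (recursively).
#' @return a [log_summary()].
#' @export
parse_logs <- function(path) {
  files <- list.files(path, pattern = "\\.json$", recursive = TRUE,
                      full.names = TRUE)
  files <- files[grepl("quant|permit|map|info", basename(files),
                       ignore.case = TRUE)]
  tabs <- list()
  for (f in files) {
    parsed <- tryCatch(jsonlite::read_json(f),
                       error = function(e) {
                         warnf("could not parse log file '%s': %s",
                               basename(f), conditionMessage(e))
                         NULL
                       })
    if (!is.null(parsed)) tabs[[basename(f)]] <- parsed
  }
  if (!length(tabs)) return(log_summary())

  num <- function(x) if (is.null(x)) NA_real_ else suppressWarnings(as.numeric(x))
  chr <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  versions <- character(); args <- character()
  for (tab in tabs) {
    for (k in names(tab)) {
      if (grepl("version", k, ignore.case = TRUE) && !is.list(tab[[k]]))
        versions[[k]] <- as.character(tab[[k]])
      if (grepl("cmd|command|arg", k, ignore.case = TRUE) && !is.list(tab[[k]]))
        args[[k]] <- as.character(tab[[k]])
    }
  }
  log_summary(
    num_processed_reads = num(log_pick(tabs, c(
      "num_processed", "num_processed_reads", "num_reads", "total_reads"))),
    num_mapped_reads = num(log_pick(tabs, c(
      "num_mapped", "num_mapped_reads", "mapped_reads"))),
    num_processed_barcodes = num(log_pick(tabs, c(
      "num_barcodes", "num_processed_barcodes", "num-barcodes",
      "corrected_barcodes", "total_barcodes"))),
    chemistry = chr(log_pick(tabs, c("chemistry", "chem"))),
    tool_versions = versions,
    command_arguments = args,
    raw_log_tables = tabs
  )
}
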