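# Scalar and per-barcode QC statistics for the report summary and plots.

#' Sequencing saturation
#'
#' Fraction of mapped reads that were UMI duplicates:
#' `1 - n_dedup_umis / n_mapped_reads` (0 when no reads were mapped). High
#' saturation means deeper sequencing would uncover few new molecules.
#'
#' @param n_mapped_reads mapped read count.
#' @param n_dedup_umis deduplicated (unique) UMI count, `<= n_mapped_reads`.
#' @return fraction in `[0, 1]`.
#' @export
sequencing_saturation <- function(n_mapped_reads, n_dedup_umis) {
  if (n_mapped_reads < 0 || n_dedup_umis < 0) stopf("counts must be non-negative")
  if (n_dedup_umis > n_mapped_reads)
    stopf("more unique UMIs (%g) than mapped reads (%g)",
          n_dedup_umis, n_mapped_reads)
  if (n_mapped_reads == 0) return(0)
  1 - n_dedup_umis / n_mapped_reads
}

#' Spliced ratio
#'
#' `(S + A) / (S + U + A)`: the proportion of spliced transcripts, with
#' ambiguous counts grouped with spliced (ambiguous reads are, in
#' expectation, most likely of spliced origin). Low values indicate nuclei
#' rather than whole cells.
#'
#' @param S,U,A spliced, unspliced, ambiguous UMI counts (vectorized).
#' @return fraction in `[0, 1]`, `NA` where `S + U + A == 0`.
#' @export
spliced_ratio <- function(S, U, A) {
  tot <- S + U + A
  out <- ifelse(tot > 0, (S + A) / tot, NA_real_)
  if (length(out) == 1L) as.numeric(out) else out
}

#' Identify mitochondrial genes
#'
#' Matches the conventional "MT-"/"mt-" symbol prefix when symbols are
#' available (falling back to the identifiers), or takes an explicit list.
#'
#' @param bundle a [quant_bundle()].
#' @param mito_genes optional explicit character vector of mitochondrial
#'   gene identifiers or symbols.
#' @return logical mask over the gene axis.
#' @export
mito_gene_mask <- function(bundle, mito_genes = NULL) {
  if (!is.null(mito_genes)) {
    mask <- bundle$genes %in% mito_genes
    if (!is.null(bundle$gene_symbols))
      mask <- mask | bundle$gene_symbols %in% mito_genes
    return(mask)
  }
  nm <- if (!is.null(bundle$gene_symbols)) bundle$gene_symbols else bundle$genes
  grepl("^(MT|mt|Mt)-", nm)
}

#' Per-barcode mitochondrial fraction
#'
#' Mitochondrial UMIs over total UMIs per barcode (0 for empty barcodes).
#' Stored as annotation only; never used here to filter cells.
#'
#' @param bundle a [quant_bundle()].
#' @param mask logical mask over genes (see [mito_gene_mask()]).
#' @return fraction vector in `[0, 1]`, one per barcode.
#' @export
mito_fraction <- function(bundle, mask = mito_gene_mask(bundle)) {
  if (length(mask) != ncol(bundle$counts))
    stopf("mito mask length does not match the gene axis")
  totals <- barcode_totals(bundle)
  mito <- if (any(mask))
    unname(Matrix::rowSums(bundle$counts[, mask, drop = FALSE]))
  else rep(0, length(totals))
  ifelse(totals > 0, mito / totals, 0)
}

#' Knee-plot series
#'
#' Descending value-vs-rank series with 1-based ranks, run-length
#' compressed for plotting (plateaus keep only their first and last rank)
#' and with zero values dropped (log-scale safety).
#'
#' @param values per-barcode counts (UMIs or genes detected), in
#'   descending-rank order; a [rank_barcodes()] result also works.
#' @return data.frame with columns `rank`, `value`.
#' @export
knee_curve <- function(values) {
  if (inherits(values, "barcode_ranking")) values <- values$counts
  if (!length(values)) stopf("empty ranking")
  values <- sort(as.numeric(values), decreasing = TRUE)
  keep <- values > 0
  values <- values[keep]
  if (!length(values)) return(data.frame(rank = integer(0), value = numeric(0)))
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rank <- unique(as.integer(rbind(starts, ends)))  # keep plateau endpoints
  rank <- sort(rank)
  data.frame(rank = rank, value = values[rank])
}

#' Per-barcode QC table
#'
#' @param bundle a [quant_bundle()].
#' @param calls optional [call_cells()] result; adds calling-outcome
#'   columns (`ordmag_retained`, `ed_pvalue`, `ed_fdr`, `retained`).
#' @param mito_genes optional explicit mitochondrial gene list.
#' @return data.frame with one row per barcode, in barcode-file order:
#'   `barcode`, `total_umis`, `genes_detected`, `mito_frac`, `rank`
#'   (position in UMI-descending order), `spliced_ratio` (USA bundles
#'   only), plus calling columns when `calls` is given.
#' @export
per_barcode_qc <- function(bundle, calls = NULL, mito_genes = NULL) {
  totals <- barcode_totals(bundle)
  genes_det <- unname(Matrix::rowSums(bundle$counts > 0))
  ord <- order(totals, decreasing = TRUE, method = "radix")
  rank <- integer(length(totals)); rank[ord] <- seq_along(totals)
  out <- data.frame(
    barcode = bundle$barcodes,
    total_umis = totals,
    genes_detected = genes_det,
    mito_frac = mito_fraction(bundle, mito_gene_mask(bundle, mito_genes)),
    rank = rank,
    stringsAsFactors = FALSE)
  if (has_usa_layers(bundle)) {
    out$spliced_ratio <- spliced_ratio(
      unname(Matrix::rowSums(bundle$layer_S)),
      unname(Matrix::rowSums(bundle$layer_U)),
      unname(Matrix::rowSums(bundle$layer_A)))
  }
  if (!is.null(calls)) {
    n <- length(totals)
    out$ordmag_retained <- seq_len(n) %in% calls$ordmag$retained_indices
    pv <- rep(NA_real_, n); fdr <- rep(NA_real_, n)
    ci <- calls$emptydrops$candidate_indices
    pv[ci] <- calls$emptydrops$p_values
    fdr[ci] <- calls$emptydrops$fdr
    out$ed_pvalue <- pv
    out$ed_fdr <- fdr
    out$retained <- seq_len(n) %in% calls$retained
  }
  out
}

#' Summary QC statistics
#'
#' The scalar metrics of the report's summary table. Medians are over
#' retained cells only; read-derived metrics (mean reads per cell,
#' saturation, mapping rate) require parsed logs and are `NA` otherwise.
#'
#' @param bundle a [quant_bundle()].
#' @param calls a [call_cells()] result.
#' @param logs a [log_summary()]; defaults to the bundle's.
#' @return object of class `qc_summary` with fields `n_retained_cells`,
#'   `n_processed_barcodes`, `mean_reads_per_cell`,
#'   `median_umis_per_cell`, `median_genes_per_cell`,
#'   `total_genes_detected`, `sequencing_saturation`, `mapping_rate`.
#' @export
summarize_qc <- function(bundle, calls, logs = bundle$log_meta) {
  totals <- barcode_totals(bundle)
  ret <- calls$retained
  n_ret <- length(ret)
  n_proc <- nrow(bundle$counts)
  if (!is.na(logs$num_processed_barcodes) &&
      logs$num_processed_barcodes != n_proc) {
    warnf("matrix has %d barcodes but logs report %g processed barcodes",
          n_proc, logs$num_processed_barcodes)
  }
  if (n_ret == 0) {
    warnf("zero retained cells: per-cell medians are undefined")
    med_umis <- med_genes <- NA_real_
    tot_genes <- 0L
  } else {
    sub <- bundle$counts[ret, , drop = FALSE]
    med_umis <- stats::median(totals[ret])
    med_genes <- stats::median(unname(Matrix::rowSums(sub > 0)))
    tot_genes <- sum(Matrix::colSums(sub) > 0)
  }
  has_reads <- !is.na(logs$num_processed_reads)
  has_mapped <- !is.na(logs$num_mapped_reads)
  structure(list(
    n_retained_cells = n_ret,
    n_processed_barcodes = n_proc,
    mean_reads_per_cell = if (has_reads && n_ret > 0)
      logs$num_processed_reads / n_ret else NA_real_,
    median_umis_per_cell = med_umis,
    median_genes_per_cell = med_genes,
    total_genes_detected = tot_genes,
    sequencing_saturation = if (has_mapped)
      sequencing_saturation(logs$num_mapped_reads, sum(totals)) else NA_real_,
    mapping_rate = if (has_reads && has_mapped && logs$num_processed_reads > 0)
      logs$num_mapped_reads / logs$num_processed_reads else NA_real_
  ), class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  num <- function(v) if (is.na(v)) "NA" else format(v, big.mark = ",")
  cat("QC summary\n")
  cat("  retained cells:        ", num(x$n_retained_cells), "\n")
  cat("  processed barcodes:    ", num(x$n_processed_barcodes), "\n")
  cat("  mean reads / cell:     ", num(round(x$mean_reads_per_cell, 1)), "\n")
  cat("  median UMIs / cell:    ", num(x$median_umis_per_cell), "\n")
  cat("  median genes / cell:   ", num(x$median_genes_per_cell), "\n")
  cat("  total genes detected:  ", num(x$total_genes_detected), "\n")
  cat("  sequencing saturation: ", pct(x$sequencing_saturation), "\n")
  cat("  mapping rate:          ", pct(x$mapping_rate), "\n")
  invisible(x)
}
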