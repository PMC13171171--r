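# Assembles the QC report: a single self-contained HTML file with a
# Summary table, the plot sections, and the raw log tables. Plots are
# rendered to inline SVG (base graphics on the cairo SVG device), so the
# file opens offline. Any section whose inputs are unavailable is marked
# skipped with a reason instead of failing the report.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

fmt_count <- function(x) {
  if (is.null(x) || is.na(x)) "not available"
  else format(round(as.numeric(x), 1), big.mark = ",", scientific = FALSE)
}
fmt_pct <- function(x) {
  if (is.null(x) || is.na(x)) "not available" else sprintf("%.1f%%", 100 * x)
}

# render base-graphics drawing code to an inline-able SVG string
svg_snippet <- function(draw, width = 6.5, height = 4.2) {
  f <- tempfile(fileext = ".svg")
  on.exit(unlink(f))
  grDevices::svg(f, width = width, height = height)
  ok <- tryCatch({ draw(); TRUE },
                 error = function(e) { warnf("plot failed: %s",
                                             conditionMessage(e)); FALSE })
  grDevices::dev.off()
  if (!ok || !file.exists(f)) return(NULL)
  txt <- readLines(f, warn = FALSE)
  paste(txt[!grepl("^<\\?xml|^<!DOCTYPE", txt)], collapse = "\n")
}

#' Assemble the report contents
#'
#' Populates every section computable from the available inputs; sections
#' whose inputs are absent (no logs, no S/U/A layers, no embeddings, no
#' doublets) are marked skipped with a reason string. The knee payload
#' records the cell-calling cutoff rank.
#'
#' @param bundle a [quant_bundle()].
#' @param calls a [call_cells()] result, or `NULL`.
#' @param qc a [summarize_qc()] result, or `NULL`.
#' @param doublets a `doublet_result`, or `NULL`.
#' @param embeddings an `embedding_result`, or `NULL`.
#' @return object of class `report_bundle` with `summary`, `plot_payloads`,
#'   `log_tables`, `skipped` (named reason strings) and `provenance`.
#' @export
build_report <- function(bundle, calls = NULL, qc = NULL, doublets = NULL,
                         embeddings = NULL) {
  payloads <- list()
  skipped <- character()
  totals <- barcode_totals(bundle)
  genes_det <- unname(Matrix::rowSums(bundle$counts > 0))
  cutoff <- if (!is.null(calls)) length(calls$retained) else NA_integer_

  payloads$knee_umi <- list(series = knee_curve(totals), cutoff_rank = cutoff)
  payloads$knee_genes <- list(series = knee_curve(genes_det),
                              cutoff_rank = cutoff)
  payloads$umi_vs_genes <- list(total_umis = totals, genes_detected = genes_det)

  lm <- bundle$log_meta
  if (!is.na(lm$num_mapped_reads)) {
    payloads$barcode_collapsing <- list(
      mapped_reads = lm$num_mapped_reads, dedup_umis = sum(totals),
      saturation = sequencing_saturation(lm$num_mapped_reads, sum(totals)))
  } else {
    skipped["barcode_collapsing"] <- "no mapped-read count in the logs"
  }

  if (has_usa_layers(bundle)) {
    S <- unname(Matrix::rowSums(bundle$layer_S))
    U <- unname(Matrix::rowSums(bundle$layer_U))
    A <- unname(Matrix::rowSums(bundle$layer_A))
    payloads$usa_bar <- list(S = sum(S), U = sum(U), A = sum(A))
    sel <- if (!is.null(calls)) calls$retained else which(totals > 0)
    payloads$spliced_hist <- list(
      ratios = spliced_ratio(S[sel], U[sel], A[sel]))
  } else {
    skipped["usa_bar"] <- "no splice-aware S/U/A layers in the input"
    skipped["spliced_hist"] <- "no splice-aware S/U/A layers in the input"
  }

  mito <- mito_fraction(bundle)
  sel <- if (!is.null(calls)) calls$retained else which(totals > 0)
  payloads$mito_hist <- list(fractions = mito[sel])

  if (!is.null(embeddings)) {
    payloads$embeddings <- list(umap = embeddings$coordinates_umap,
                                tsne = embeddings$coordinates_tsne)
  } else {
    skipped["embeddings"] <- "embeddings not computed"
  }
  if (!is.null(doublets)) {
    payloads$doublets <- list(observed = doublets$observed_scores,
                              simulated = doublets$simulated_scores,
                              threshold = doublets$threshold)
  } else {
    skipped["doublets"] <- "doublet scoring not computed"
  }
  if (is.null(qc)) skipped["summary"] <- "summary statistics not computed"

  structure(list(
    summary = qc,
    plot_payloads = payloads,
    log_tables = lm$raw_log_tables,
    skipped = skipped,
    provenance = list(tool = "umiqc", version = "0.1.0",
                      parameters = if (!is.null(calls)) calls$parameters else NULL)
  ), class = "report_bundle")
}

summary_rows <- function(qc) {
  list(
    c("Retained cells", fmt_count(qc$n_retained_cells)),
    c("Processed barcodes", fmt_count(qc$n_processed_barcodes)),
    c("Mean reads per cell", fmt_count(qc$mean_reads_per_cell)),
    c("Median UMIs per cell", fmt_count(qc$median_umis_per_cell)),
    c("Median genes per cell", fmt_count(qc$median_genes_per_cell)),
    c("Total genes detected", fmt_count(qc$total_genes_detected)),
    c("Sequencing saturation", fmt_pct(qc$sequencing_saturation)),
    c("Mapping rate", fmt_pct(qc$mapping_rate)))
}

section_html <- function(id, title, body) {
  sprintf('<section id="%s">\n<h2>%s</h2>\n%s\n</section>', id, title, body)
}
skipped_html <- function(id, title, reason) {
  sprintf('<section id="%s" class="skipped">\n<h2>%s</h2>\n<p class="skip-reason">Section skipped: %s.</p>\n</section>',
          id, title, html_escape(reason))
}

loglog_knee_svg <- function(payload, ylab) {
  s <- payload$series
  if (!nrow(s)) return(NULL)
  svg_snippet(function() {
    graphics::plot(s$rank, s$value, log = "xy", type = "l", lwd = 2,
                   col = "#2c7fb8", xlab = "barcode rank (log10)",
                   ylab = paste(ylab, "(log10)"),
                   main = paste("Ranked", ylab))
    if (!is.na(payload$cutoff_rank) && payload$cutoff_rank >= 1)
      graphics::abline(v = payload$cutoff_rank, lty = 2, col = "#de2d26")
  })
}

hist_svg <- function(x, xlab, main, vline = NULL) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NULL)
  svg_snippet(function() {
    graphics::hist(x, breaks = 40, col = "#a6bddb", border = "white",
                   xlab = xlab, main = main)
    if (!is.null(vline) && is.finite(vline))
      graphics::abline(v = vline, lty = 2, col = "#de2d26")
  })
}

#' Render the report to a self-contained HTML file
#'
#' One HTML5 file, assets inlined, no network access needed to view it.
#' Deterministic for identical report contents apart from the timestamp.
#'
#' @param report a [build_report()] result.
#' @param path output file path.
#' @param timestamp timestamp string stamped into the footer; defaults to
#'   the current time (pass a fixed value for reproducible output).
#' @return `path`, invisibly.
#' @export
render_html <- function(report, path,
                        timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S")) {
  p <- report$plot_payloads
  sk <- report$skipped
  out <- character()

  out <- c(out, if (is.null(report$summary))
    skipped_html("summary", "Summary", sk[["summary"]])
  else {
    rows <- summary_rows(report$summary)
    tab <- paste(vapply(rows, function(r)
      sprintf("<tr><td>%s</td><td>%s</td></tr>", r[1], r[2]), character(1)),
      collapse = "\n")
    section_html("summary", "Summary",
                 sprintf("<table class=\"summary\">\n%s\n</table>", tab))
  })

  knee1 <- loglog_knee_svg(p$knee_umi, "UMI counts")
  knee2 <- loglog_knee_svg(p$knee_genes, "genes detected")
  out <- c(out, section_html("knee_plots", "Knee plots",
    paste(c("<p>Ranked per-barcode UMI counts and detected genes; the dashed line marks the cell-calling cutoff rank.</p>",
            knee1, knee2), collapse = "\n")))

  sc <- p$umi_vs_genes
  scat <- svg_snippet(function() {
    keep <- sc$total_umis > 0
    graphics::plot(sc$total_umis[keep], pmax(sc$genes_detected[keep], 1),
                   log = "xy", pch = 16, cex = 0.4, col = "#00000055",
                   xlab = "total UMIs (log10)", ylab = "genes detected (log10)",
                   main = "Gene detection vs depth")
  })
  out <- c(out, section_html("umi_counts", "UMI counts",
    paste(c("<p>Gene detection should rise with depth and plateau; outliers high above the trend can indicate multiplets.</p>", scat), collapse = "\n")))

  out <- c(out, if (is.null(p$barcode_collapsing))
    skipped_html("barcode_collapsing", "Barcode collapsing",
                 sk[["barcode_collapsing"]])
  else {
    bc <- p$barcode_collapsing
    bar <- svg_snippet(function() {
      graphics::barplot(c(`mapped reads` = bc$mapped_reads,
                          `unique UMIs` = bc$dedup_umis),
                        col = c("#2c7fb8", "#a6bddb"),
                        main = "Reads vs deduplicated UMIs")
    })
    section_html("barcode_collapsing", "Barcode collapsing",
      paste(c(sprintf("<p>Sequencing saturation (duplicate-read fraction): <b>%s</b>.</p>",
                      fmt_pct(bc$saturation)), bar), collapse = "\n"))
  })

  out <- c(out, if (is.null(p$usa_bar))
    skipped_html("usa_bar", "Splice-status composition", sk[["usa_bar"]])
  else {
    bar <- svg_snippet(function() {
      graphics::barplot(c(S = p$usa_bar$S, U = p$usa_bar$U, A = p$usa_bar$A),
                        col = c("#31a354", "#fdae6b", "#bdbdbd"),
                        main = "Total UMIs per splice status")
    })
    section_html("usa_bar", "Splice-status composition",
      paste(c("<p>Total UMIs assigned spliced (S), unspliced (U) and ambiguous (A) status.</p>", bar), collapse = "\n"))
  })

  out <- c(out, if (is.null(p$spliced_hist))
    skipped_html("spliced_hist", "Spliced ratio", sk[["spliced_hist"]])
  else section_html("spliced_hist", "Spliced ratio",
    paste(c("<p>Per-cell (S + A) / (S + U + A). Whole cells are dominated by spliced transcripts; nuclei samples shift toward low values.</p>",
            hist_svg(p$spliced_hist$ratios, "spliced ratio", "Spliced ratio per cell")),
          collapse = "\n")))

  out <- c(out, section_html("mito", "Mitochondrial content",
    paste(c("<p>Per-cell mitochondrial UMI fraction. A 10% threshold is a common guideline for damaged or dying cells in human samples; it is reported here for assessment only and never applied as an automatic filter.</p>",
            hist_svg(p$mito_hist$fractions, "mitochondrial fraction",
                     "Mitochondrial content", vline = 0.1)), collapse = "\n")))

  out <- c(out, if (is.null(p$doublets))
    skipped_html("doublets", "Doublet scores", sk[["doublets"]])
  else section_html("doublets", "Doublet scores",
    paste(c("<p>Observed-cell doublet scores with the threshold from the simulated-score distribution (dashed).</p>",
            hist_svg(p$doublets$observed, "doublet score", "Observed doublet scores",
                     vline = p$doublets$threshold)), collapse = "\n")))

  out <- c(out, if (is.null(p$embeddings))
    skipped_html("embeddings", "Embeddings", sk[["embeddings"]])
  else {
    draw2 <- function(xy, main) svg_snippet(function() {
      graphics::plot(xy[, 1], xy[, 2], pch = 16, cex = 0.5, col = "#00000077",
                     xlab = paste0(main, " 1"), ylab = paste0(main, " 2"),
                     main = main)
    })
    section_html("embeddings", "Embeddings",
      paste(c("<p>2-D projections of retained cells; proximity reflects transcriptomic similarity.</p>",
              draw2(p$embeddings$umap, "UMAP"),
              draw2(p$embeddings$tsne, "t-SNE")), collapse = "\n"))
  })

  out <- c(out, if (!length(report$log_tables))
    skipped_html("log_info", "Log info", "no log files were found in the input")
  else {
    tabs <- vapply(names(report$log_tables), function(nm) {
      tab <- report$log_tables[[nm]]
      flat <- tab[!vapply(tab, is.list, logical(1))]
      rows <- paste(vapply(names(flat), function(k)
        sprintf("<tr><td>%s</td><td>%s</td></tr>", html_escape(k),
                html_escape(paste(format(flat[[k]]), collapse = ", "))),
        character(1)), collapse = "\n")
      sprintf("<h3>%s</h3>\n<table class=\"log\">\n%s\n</table>",
              html_escape(nm), rows)
    }, character(1))
    section_html("log_info", "Log info", paste(tabs, collapse = "\n"))
  })

  prov <- report$provenance
  html <- paste(c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\">",
    "<title>umiqc report</title>",
    "<style>body{font-family:sans-serif;max-width:960px;margin:auto;padding:1em;} table{border-collapse:collapse;} td{border:1px solid #ccc;padding:4px 10px;} section{margin-bottom:2em;} .skipped h2{color:#999;} .skip-reason{color:#999;font-style:italic;}</style>",
    "</head><body>",
    "<h1>umiqc quality-control report</h1>",
    out,
    sprintf("<footer><p>%s %s &middot; generated %s</p></footer>",
            prov$tool, prov$version, timestamp),
    "</body></html>"), collapse = "\n")
  writeLines(html, path)
  invisible(path)
}
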