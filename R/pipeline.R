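#' Run the full QC pipeline
#'
#' Loads a quantification directory (or `.h5ad` file), calls cells,
#' computes QC statistics, optionally scores doublets and embeds cells,
#' renders the HTML report, and exports the annotated HDF5 matrix.
#' Stage failures in the optional doublet/embedding steps downgrade to
#' warnings so the report is always produced.
#'
#' @param input quantification directory or `.h5ad` file path.
#' @param output_dir directory for the report and exported matrix.
#' @param report_name report file name (default `"qc_report.html"`).
#' @param umi_floor,fdr_threshold,chemistry,n_simulations,seed,ambient_max,grid_points
#'   cell-calling settings, see [call_cells()].
#' @param skip_embed skip the doublet/embedding stage (default `FALSE`).
#' @param n_sim_doublets simulated doublet count (default 2x retained).
#' @param knn_k neighbour count for doublet scoring.
#' @param exclude_doublets drop flagged doublets before embedding.
#' @param mito_genes optional explicit mitochondrial gene list.
#' @return list with `bundle`, `calls`, `qc`, `doublets`, `embeddings`,
#'   and the output `report_path` / `h5_path`, invisibly.
#' @export
run_pipeline <- function(input, output_dir, report_name = "qc_report.html",
                         umi_floor = 500, fdr_threshold = NULL,
                         chemistry = NULL, n_simulations = 10000L, seed = 0L,
                         ambient_max = NULL, grid_points = 2000L,
                         skip_embed = FALSE, n_sim_doublets = NULL,
                         knn_k = 15L, exclude_doublets = FALSE,
                         mito_genes = NULL) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- if (dir.exists(input)) load_quant_dir(input)
            else load_h5_input(input)
  calls <- call_cells(bundle, umi_floor = umi_floor,
                      fdr_threshold = fdr_threshold, chemistry = chemistry,
                      n_simulations = n_simulations, seed = seed,
                      ambient_max = ambient_max, grid_points = grid_points)
  qc <- summarize_qc(bundle, calls)

  doublets <- NULL
  embeddings <- NULL
  if (!skip_embed) {
    doublets <- tryCatch(
      detect_doublets(bundle, calls, n_simulated = n_sim_doublets,
                      k = knn_k, seed = seed),
      error = function(e) {
        warnf("doublet scoring failed: %s", conditionMessage(e)); NULL
      })
    embeddings <- tryCatch(
      embed_cells(bundle$counts[calls$retained, , drop = FALSE],
                  doublets = doublets, exclude_doublets = exclude_doublets,
                  seed = seed),
      error = function(e) {
        warnf("embedding failed: %s", conditionMessage(e)); NULL
      })
  }

  report <- build_report(bundle, calls, qc, doublets, embeddings)
  report_path <- file.path(output_dir, report_name)
  render_html(report, report_path)
  h5_path <- file.path(output_dir, "quants_annotated.h5ad")
  export_h5(bundle, calls, qc, doublets, h5_path, mito_genes = mito_genes)

  invisible(list(bundle = bundle, calls = calls, qc = qc,
                 doublets = doublets, embeddings = embeddings,
                 report_path = report_path, h5_path = h5_path))
}
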