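# Fixture builders used across test files. Everything is generated in
# code; nothing is read from disk except what the tests themselves write.

# tiny splice-aware quantification directory: 3 barcodes x 2 genes, with
# barcode b1 carrying (S:2, U:1, A:1) on gene g1
write_tiny_usa_dir <- function(dir = tempfile("usa_fix_")) {
  dir.create(dir)
  # columns: g1, g2, g1-U, g2-U, g1-A, g2-A
  mat <- Matrix::sparseMatrix(
    i = c(1, 1, 1, 2, 3),
    j = c(1, 3, 5, 2, 1),
    x = c(2, 1, 1, 5, 7), dims = c(3, 6))
  Matrix::writeMM(mat, file.path(dir, "quants_mat.mtx"))
  writeLines(c("b1", "b2", "b3"), file.path(dir, "quants_mat_rows.txt"))
  writeLines(c("g1", "g2", "g1-U", "g2-U", "g1-A", "g2-A"),
             file.path(dir, "quants_mat_cols.txt"))
  dir
}

# plain (non-splice-aware) directory with optional log files
write_tiny_plain_dir <- function(dir = tempfile("plain_fix_"),
                                 with_logs = TRUE) {
  dir.create(dir)
  mat <- Matrix::sparseMatrix(i = c(1, 2, 2), j = c(1, 1, 2),
                              x = c(3, 1, 4), dims = c(2, 2))
  Matrix::writeMM(mat, file.path(dir, "quants_mat.mtx"))
  writeLines(c("b1", "b2"), file.path(dir, "quants_mat_rows.txt"))
  writeLines(c("g1", "g2"), file.path(dir, "quants_mat_cols.txt"))
  if (with_logs) {
    jsonlite::write_json(list(num_processed = 1000, num_mapped = 900,
                              chemistry = "10xv3"),
                         file.path(dir, "quant.json"), auto_unbox = TRUE)
    jsonlite::write_json(list(num_barcodes = 2, permit_list_version = "t0"),
                         file.path(dir, "generate_permit_list.json"),
                         auto_unbox = TRUE)
  }
  dir
}

# bimodal bundle with a clean knee: n_high barcodes from a "cell" profile
# at high depth, n_low ambient barcodes at low depth, plus optional
# mid-range barcodes drawn from either profile (for the rescue test)
make_rescue_bundle <- function(n_high = 50, high_depth = 10000,
                               n_low = 500, n_mid_real = 0, n_mid_amb = 0,
                               mid_depth = 600, n_genes = 50, seed = 1) {
  stopifnot(n_genes >= 10)
  # cell program concentrated on the first half, ambient on the second
  p_cell <- c(rep(4, n_genes %/% 2), rep(0.1, n_genes - n_genes %/% 2))
  p_cell <- p_cell / sum(p_cell)
  p_amb <- c(rep(0.1, n_genes %/% 2), rep(4, n_genes - n_genes %/% 2))
  p_amb <- p_amb / sum(p_amb)
  rows <- withr_seed(seed, {
    draw <- function(n, depth_fn, prof) {
      if (n == 0) return(NULL)
      t(vapply(seq_len(n), function(i)
        stats::rmultinom(1, depth_fn(), prof)[, 1], numeric(n_genes)))
    }
    rbind(
      draw(n_high, function() high_depth + sample(-50:50, 1), p_cell),
      draw(n_mid_real, function() mid_depth + sample(-20:20, 1), p_cell),
      draw(n_mid_amb, function() mid_depth + sample(-20:20, 1), p_amb),
      draw(n_low, function() sample(1:100, 1), p_amb))
  })
  labels <- c(rep("high", n_high), rep("mid_real", n_mid_real),
              rep("mid_amb", n_mid_amb), rep("low", n_low))
  bundle <- quant_bundle(
    counts = Matrix::Matrix(rows, sparse = TRUE),
    barcodes = sprintf("BC%04d", seq_len(nrow(rows))),
    genes = sprintf("G%03d", seq_len(n_genes)))
  list(bundle = bundle, labels = labels)
}

# run expr under a seed without disturbing the session RNG
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}
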