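# Doublet scoring by simulated-doublet neighbourhoods, plus 2-D embeddings
# of retained cells via a standard normalize / log / HVG / PCA pipeline.
# UMAP and t-SNE projections delegate to the standard implementations
# (umap-learn, scikit-learn) through a bundled helper.

#' Simulate artificial doublets
#'
#' Each simulated doublet is the elementwise sum of the gene counts of two
#' distinct, uniformly sampled observed cells.
#'
#' @param counts cells-by-genes count matrix of observed (retained) cells.
#' @param n_simulated number of doublets to simulate; default twice the
#'   number of observed cells.
#' @param seed RNG seed.
#' @return list with `counts` (simulated doublets x genes, sparse) and
#'   `parents` (n_simulated x 2 matrix of parent row indices).
#' @export
simulate_doublets <- function(counts, n_simulated = 2L * nrow(counts),
                              seed = 0L) {
  n <- nrow(counts)
  if (n < 2L) stopf("need at least 2 cells to simulate doublets")
  parents <- with_seed(seed, {
    a <- sample.int(n, n_simulated, replace = TRUE)
    b <- sample.int(n - 1L, n_simulated, replace = TRUE)
    b <- b + (b >= a)  # uniform over pairs with b != a
    cbind(a, b, deparse.level = 0)
  })
  list(counts = as_dgc(counts[parents[, 1], , drop = FALSE] +
                         counts[parents[, 2], , drop = FALSE]),
       parents = parents)
}

# total-count normalization to `target`, then log1p, densified
normalize_log <- function(counts, target) {
  totals <- Matrix::rowSums(counts)
  sf <- ifelse(totals > 0, target / totals, 0)
  log1p(as.matrix(counts) * sf)
}

# brute-force k-nearest-neighbour indices (self excluded)
knn_indices <- function(x, k) {
  n <- nrow(x)
  if (k >= n) stopf("k (%d) must be smaller than the number of points (%d)", k, n)
  d2 <- as.matrix(stats::dist(x))^2
  diag(d2) <- Inf
  nn <- vapply(seq_len(n), function(i) order(d2[i, ])[seq_len(k)],
               numeric(k))
  if (k == 1L) matrix(nn, ncol = 1L) else t(nn)
}

find_bimodal_threshold <- function(scores) {
  if (length(unique(scores)) < 3L || stats::sd(scores) < 1e-8) return(NULL)
  d <- stats::density(scores, n = 512)
  y <- d$y
  i <- 2:(length(y) - 1L)
  peaks <- i[y[i] > y[i - 1L] & y[i] >= y[i + 1L]]
  peaks <- peaks[y[peaks] >= 0.05 * max(y)]  # ignore ripples
  if (length(peaks) < 2L) return(NULL)
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  valley <- seq(top2[1], top2[2])
  d$x[valley[which.min(y[valley])]]
}

#' Score cells for doublets
#'
#' Embeds observed cells and simulated doublets jointly (total-count
#' normalization to the median observed depth, log1p, PCA), builds a
#' k-nearest-neighbour graph in PC space, and scores each cell by the
#' fraction `q` of its neighbours that are simulated, rescaled to
#' `q / (r (1 - q) + q)` for the simulated:observed ratio `r`. The doublet
#' threshold is the minimum-density point between the two modes of the
#' simulated-score distribution; if that distribution is not bimodal, no
#' cells are flagged and a warning is emitted.
#'
#' @param observed cells-by-genes count matrix of observed cells.
#' @param simulated simulated-doublet matrix sharing the gene axis, e.g.
#'   from [simulate_doublets()]; `NULL` simulates `2 * nrow(observed)`.
#' @param k neighbour count (default 15).
#' @param n_pcs PCA dimensions for the joint embedding (default 30).
#' @param seed RNG seed for simulation.
#' @return object of class `doublet_result`: `observed_scores`,
#'   `simulated_scores`, `threshold` (`Inf` when unimodal), `is_doublet`,
#'   `n_simulated`, `seed`, `parents`.
#' @export
doublet_scores <- function(observed, simulated = NULL, k = 15L, n_pcs = 30L,
                           seed = 0L) {
  if (is.null(simulated)) simulated <- simulate_doublets(observed, seed = seed)
  parents <- NULL
  if (is.list(simulated) && !is.null(simulated$counts)) {
    parents <- simulated$parents
    simulated <- simulated$counts
  }
  if (ncol(simulated) != ncol(observed))
    stopf("observed and simulated gene axes differ")
  n_obs <- nrow(observed); n_sim <- nrow(simulated)
  target <- stats::median(Matrix::rowSums(observed))
  joint <- rbind(normalize_log(observed, target),
                 normalize_log(simulated, target))
  n_pcs <- min(n_pcs, ncol(joint), nrow(joint) - 1L)
  pcs <- stats::prcomp(joint, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  nn <- knn_indices(pcs, k)
  is_sim <- c(rep(FALSE, n_obs), rep(TRUE, n_sim))
  q <- rowMeans(matrix(is_sim[nn], nrow = nrow(nn)))
  r <- n_sim / n_obs
  score <- q / (r * (1 - q) + q)
  obs_scores <- score[seq_len(n_obs)]
  sim_scores <- score[n_obs + seq_len(n_sim)]

  threshold <- find_bimodal_threshold(sim_scores)
  if (is.null(threshold)) {
    warnf("simulated doublet scores are not bimodal; flagging no doublets")
    threshold <- Inf
  }
  structure(list(
    observed_scores = obs_scores, simulated_scores = sim_scores,
    threshold = threshold, is_doublet = obs_scores > threshold,
    n_simulated = n_sim, seed = as.integer(seed), parents = parents
  ), class = "doublet_result")
}

#' Doublet detection on called cells
#'
#' Convenience wrapper: subsets the bundle to retained cells, simulates
#' doublets and scores them ([doublet_scores()]).
#'
#' @param bundle a [quant_bundle()].
#' @param calls a [call_cells()] result.
#' @param n_simulated simulated doublet count (default 2x retained).
#' @param ... forwarded to [doublet_scores()].
#' @param seed RNG seed.
#' @return a `doublet_result` with `cell_indices` (original barcode
#'   indices of the scored cells) attached.
#' @export
detect_doublets <- function(bundle, calls, n_simulated = NULL, seed = 0L, ...) {
  obs <- bundle$counts[calls$retained, , drop = FALSE]
  if (is.null(n_simulated)) n_simulated <- 2L * nrow(obs)
  sim <- simulate_doublets(obs, n_simulated = n_simulated, seed = seed)
  res <- doublet_scores(obs, sim, seed = seed, ...)
  res$cell_indices <- calls$retained
  res
}

# dispersion-based highly-variable gene selection on log-normalized data
select_hvg <- function(logmat, n_hvg) {
  mu <- colMeans(logmat)
  v <- apply(logmat, 2L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  order(disp, decreasing = TRUE)[seq_len(min(n_hvg, ncol(logmat)))]
}

#' 2-D embeddings of retained cells
#'
#' Standard pipeline: total-count normalization to the median depth,
#' log1p, top-`n_hvg` highly-variable genes by dispersion, PCA, then UMAP
#' and t-SNE with fixed seeds via the reference implementations. Inputs
#' below `min_cells` cells, or with a degenerate gene axis, skip the
#' embedding with a warning rather than failing.
#'
#' @param counts cells-by-genes count matrix of retained cells.
#' @param n_hvg highly-variable gene count (default 2000).
#' @param n_pcs PCA dimensions (default 30).
#' @param n_neighbors UMAP neighbour count (default 15).
#' @param min_cells minimum viable cell count (default 30).
#' @param doublets optional `doublet_result`; flagged cells are excluded
#'   first when `exclude_doublets` is `TRUE`.
#' @param exclude_doublets logical (default `FALSE`).
#' @param seed RNG seed.
#' @return object of class `embedding_result` with `coordinates_umap`,
#'   `coordinates_tsne` (n x 2 matrices, `NULL` when skipped),
#'   `cell_mask` (which input rows were embedded) and `pipeline_params`;
#'   or `NULL` when skipped entirely.
#' @export
embed_cells <- function(counts, n_hvg = 2000L, n_pcs = 30L, n_neighbors = 15L,
                        min_cells = 30L, doublets = NULL,
                        exclude_doublets = FALSE, seed = 0L) {
  keep <- rep(TRUE, nrow(counts))
  if (exclude_doublets && !is.null(doublets)) keep <- !doublets$is_doublet
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) < min_cells) {
    warnf("only %d cells (< %d); skipping embeddings", nrow(counts), min_cells)
    return(NULL)
  }
  if (sum(Matrix::colSums(counts) > 0) < 2L) {
    warnf("fewer than 2 expressed genes; skipping embeddings")
    return(NULL)
  }
  target <- stats::median(Matrix::rowSums(counts))
  logmat <- normalize_log(counts, target)
  hvg <- select_hvg(logmat, n_hvg)
  n_pcs <- min(n_pcs, length(hvg), nrow(logmat) - 1L)
  pcs <- stats::prcomp(logmat[, hvg, drop = FALSE], center = TRUE,
                       rank. = n_pcs)$x

  pca_file <- tempfile(fileext = ".csv"); out_file <- tempfile(fileext = ".csv")
  on.exit(unlink(c(pca_file, out_file)))
  utils::write.table(pcs, pca_file, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  coords <- tryCatch({
    run_python(py_script("embed_bridge.py"),
               c(pca_file, out_file, as.character(seed),
                 as.character(n_neighbors)))
    as.matrix(utils::read.csv(out_file, header = TRUE))
  }, error = function(e) {
    warnf("embedding backend failed (%s); coordinates unavailable",
          conditionMessage(e))
    NULL
  })
  if (is.null(coords)) return(NULL)
  structure(list(
    coordinates_umap = coords[, c("umap1", "umap2"), drop = FALSE],
    coordinates_tsne = coords[, c("tsne1", "tsne2"), drop = FALSE],
    cell_mask = keep,
    pipeline_params = list(normalize_target = target, n_hvg = length(hvg),
                           n_pcs = n_pcs, n_neighbors = n_neighbors,
                           seed = as.integer(seed))
  ), class = "embedding_result")
}
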