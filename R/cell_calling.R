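# Two-stage cell calling.
#
# Stage 1 (order-of-magnitude knee estimation): for each candidate cell
# number c, take the 99th-percentile UMI count m among the top-c barcodes,
# count barcodes whose totals exceed m/10, and keep the candidate whose
# observed count matches it best under the loss (obs - c)^2 / c. The
# top-c* barcodes form the high-confidence retained set.
#
# Stage 2 (ambient rescue): barcodes outside that set with at least
# `umi_floor` UMIs are tested against the ambient-RNA multinomial profile
# estimated from low-count droplets; a Monte-Carlo p-value per barcode is
# BH-adjusted and barcodes below the FDR threshold are added to the
# retained set. Stage-1 barcodes never enter the test.

#' Rank barcodes by total UMI count
#'
#' @param bundle a [quant_bundle()] (or a numeric vector of totals).
#' @return an object of class `barcode_ranking` with `counts` (totals,
#'   non-increasing) and `order` (sorted position -> original barcode
#'   index). The sort is stable: ties keep original barcode order.
#' @export
rank_barcodes <- function(bundle) {
  totals <- if (inherits(bundle, "quant_bundle")) barcode_totals(bundle)
            else as.numeric(bundle)
  if (!length(totals) || all(totals == 0)) stopf("no counted barcodes")
  ord <- order(totals, decreasing = TRUE, method = "radix")
  structure(list(counts = totals[ord], order = ord),
            class = "barcode_ranking")
}

#' 99th-percentile UMI count
#'
#' Linear interpolation between order statistics (the usual "type 7"
#' definition), implemented directly so the top-c prefix of a descending
#' ranking can be scored without re-sorting.
#'
#' @param top_counts numeric vector of UMI totals (any order).
#' @return scalar 99th percentile.
#' @export
percentile99 <- function(top_counts) {
  n <- length(top_counts)
  if (!n) stopf("percentile of an empty list is undefined")
  if (n == 1L) return(as.numeric(top_counts))
  asc <- sort(top_counts)       # ascending order statistics
  h <- (n - 1) * 0.99
  lo <- floor(h)
  frac <- h - lo
  as.numeric(asc[lo + 1] + frac * (asc[min(lo + 2, n)] - asc[lo + 1]))
}

#' Observed cell count at a dynamic cutoff
#'
#' Number of barcodes whose total UMI count strictly exceeds `m_k / 10`.
#'
#' @param ranking a [rank_barcodes()] result.
#' @param m_k reference (99th-percentile) UMI count, `>= 0`.
#' @return integer count.
#' @export
observed_cell_count <- function(ranking, m_k) {
  if (m_k < 0) stopf("m_k must be non-negative")
  sum(ranking$counts > m_k / 10)
}

#' Knee-estimation loss
#'
#' Relative squared mismatch `(c_obs - c_exp)^2 / c_exp` between the
#' observed and the candidate cell count.
#'
#' @param c_obs observed count.
#' @param c_exp candidate count, `>= 1`.
#' @return non-negative scalar.
#' @export
ordmag_loss <- function(c_obs, c_exp) {
  if (any(c_exp < 1)) stopf("candidate cell count must be >= 1")
  (c_obs - c_exp)^2 / c_exp
}

# default candidate grid: geometric series over all magnitudes up to the
# number of nonzero barcodes
ordmag_grid <- function(n_nonzero, grid_points = 2000L) {
  g <- unique(pmin(round(10^seq(0, log10(n_nonzero), length.out = grid_points)),
                   n_nonzero))
  sort(g[g >= 1])
}

eval_ordmag <- function(ranking, candidates) {
  m_k <- vapply(candidates, function(c)
    percentile99(ranking$counts[seq_len(c)]), numeric(1))
  observed <- vapply(m_k, function(m) observed_cell_count(ranking, m), numeric(1))
  losses <- ordmag_loss(observed, candidates)
  list(m_k = m_k, observed = observed, losses = losses)
}

#' Order-of-magnitude cell-count estimation
#'
#' Evaluates the knee loss over a geometric candidate grid, then refines
#' over every integer between the grid neighbours of the coarse optimum so
#' the selected candidate is an exact integer argmin. Ties go to the
#' smallest candidate.
#'
#' @param ranking a [rank_barcodes()] result.
#' @param grid optional explicit integer candidate vector; by default a
#'   geometric series over `[1, #nonzero barcodes]`.
#' @param grid_points number of points in the default grid.
#' @param refine logical; perform the local integer refinement step.
#' @return object of class `ordmag_result`: `candidates`, `m_k`,
#'   `observed`, `losses` (parallel vectors), `expected_cells`, and
#'   `retained_indices` (original indices of the top barcodes).
#' @export
ordmag_call <- function(ranking, grid = NULL, grid_points = 2000L,
                        refine = TRUE) {
  n_nonzero <- sum(ranking$counts > 0)
  if (n_nonzero == 0L) stopf("no counted barcodes")
  if (is.null(grid)) grid <- ordmag_grid(n_nonzero, grid_points)
  grid <- sort(unique(round(grid)))
  grid <- grid[grid >= 1 & grid <= n_nonzero]
  if (!length(grid)) stopf("candidate grid empty after clipping")

  ev <- eval_ordmag(ranking, grid)
  best <- which.min(ev$losses)  # first minimum = smallest candidate on ties

  if (refine && length(grid) > 1L) {
    lo <- if (best > 1L) grid[best - 1L] + 1L else grid[best]
    hi <- if (best < length(grid)) grid[best + 1L] - 1L else grid[best]
    extra <- setdiff(seq(lo, hi), grid)
    if (length(extra)) {
      ev2 <- eval_ordmag(ranking, extra)
      grid <- c(grid, extra)
      ev <- list(m_k = c(ev$m_k, ev2$m_k),
                 observed = c(ev$observed, ev2$observed),
                 losses = c(ev$losses, ev2$losses))
      o <- order(grid)
      grid <- grid[o]
      ev <- lapply(ev, `[`, o)
      best <- which.min(ev$losses)
    }
  }

  expected <- grid[best]
  structure(list(
    candidates = grid, m_k = ev$m_k, observed = ev$observed,
    losses = ev$losses, expected_cells = expected,
    retained_indices = ranking$order[seq_len(expected)]
  ), class = "ordmag_result")
}

#' Estimate the ambient RNA expression profile
#'
#' Pools the counts of the given (presumed empty) barcodes and normalizes
#' with a per-gene pseudocount so the profile is strictly positive.
#'
#' @param bundle a [quant_bundle()].
#' @param pool integer vector of barcode indices forming the ambient pool.
#' @param pseudocount per-gene smoothing constant (default 0.5). Zero
#'   disables smoothing (test use only; genes absent from the pool then
#'   get probability zero).
#' @return probability vector over genes, summing to 1.
#' @export
estimate_ambient_profile <- function(bundle, pool, pseudocount = 0.5) {
  if (!length(pool)) stopf("cannot estimate ambient profile: empty pool")
  pooled <- Matrix::colSums(bundle$counts[pool, , drop = FALSE])
  tot <- sum(pooled) + pseudocount * length(pooled)
  if (tot <= 0) stopf("cannot estimate ambient profile: pool has no counts")
  unname((pooled + pseudocount) / tot)
}

#' Multinomial log-likelihood of a count vector
#'
#' Log probability mass of `barcode_counts` under a multinomial with the
#' vector's own total and the given gene profile, in log-gamma form.
#'
#' @param barcode_counts non-negative count vector.
#' @param profile strictly positive probability vector, same length.
#' @return scalar log-likelihood.
#' @export
multinomial_loglik <- function(barcode_counts, profile) {
  if (length(barcode_counts) != length(profile))
    stopf("counts (%d) and profile (%d) lengths differ",
          length(barcode_counts), length(profile))
  if (any(profile <= 0)) stopf("profile must be strictly positive")
  if (abs(sum(profile) - 1) > 1e-8) stopf("profile must sum to 1")
  lgamma(sum(barcode_counts) + 1) - sum(lgamma(barcode_counts + 1)) +
    sum(barcode_counts * log(profile))
}

#' Monte-Carlo p-values against the ambient profile
#'
#' Candidates are grouped by identical total UMI count; for each distinct
#' total, `n_simulations` multinomial draws from the profile are scored,
#' and each candidate's p-value is `(1 + #\{simulated loglik <= observed
#' loglik\}) / (1 + n_simulations)`. Ties in log-likelihood are counted
#' with an absolute tolerance of 1e-9. Deterministic given `seed`; the
#' caller's RNG stream is left untouched.
#'
#' @param candidates matrix (candidates x genes) of count vectors.
#' @param profile strictly positive probability vector over genes.
#' @param n_simulations Monte-Carlo iterations per distinct total
#'   (default 10000).
#' @param seed RNG seed (default 0).
#' @return p-value vector, one per candidate row, each in `(0, 1]`.
#' @export
montecarlo_pvalues <- function(candidates, profile, n_simulations = 10000L,
                               seed = 0L) {
  if (n_simulations < 1) stopf("n_simulations must be >= 1")
  candidates <- as.matrix(candidates)
  if (!nrow(candidates)) return(numeric(0))
  obs_ll <- apply(candidates, 1L, multinomial_loglik, profile = profile)
  totals <- rowSums(candidates)
  logp <- log(profile)
  p <- numeric(nrow(candidates))
  with_seed(seed, {
    for (tt in sort(unique(totals))) {
      sims <- stats::rmultinom(n_simulations, tt, profile)  # genes x n_sims
      sim_ll <- lgamma(tt + 1) - colSums(lgamma(sims + 1)) + colSums(sims * logp)
      idx <- which(totals == tt)
      for (i in idx)
        p[i] <- (1 + sum(sim_ll <= obs_ll[i] + 1e-9)) / (1 + n_simulations)
    }
  })
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, clipped to 1, order-preserving with input.
#'
#' @param p p-value vector, all in `(0, 1]`.
#' @return adjusted (FDR) vector of the same length.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stopf("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-stage cell calling
#'
#' Runs [rank_barcodes()] and [ordmag_call()], then tests every barcode
#' outside the knee-retained set with at least `umi_floor` total UMIs
#' against the ambient multinomial profile ([montecarlo_pvalues()]), and
#' adds barcodes passing the BH-FDR threshold to the retained set.
#' Knee-retained barcodes bypass the test entirely.
#'
#' @param bundle a [quant_bundle()].
#' @param umi_floor minimum total UMIs for a rescue candidate (default 500).
#' @param fdr_threshold explicit FDR cutoff; when `NULL` it is 0.001 if
#'   `chemistry` is listed in `strict_chemistries`, else 0.01.
#' @param chemistry chemistry tag; defaults to the bundle's parsed logs.
#' @param strict_chemistries character vector of chemistry tags that map
#'   to the stricter 0.001 threshold (default none).
#' @param n_simulations,seed Monte-Carlo settings.
#' @param ambient_max upper UMI bound of the ambient pool; default
#'   `min(100, umi_floor / 5)`.
#' @param pseudocount ambient-profile smoothing (default 0.5).
#' @param grid,grid_points forwarded to [ordmag_call()].
#' @return object of class `cell_calls`: `ordmag`, `emptydrops` (with
#'   `candidate_indices`, `log_likelihoods`, `p_values`, `fdr`,
#'   `threshold_used`, `n_simulations`, `seed`), `retained` (final
#'   original-index set), and `parameters`.
#' @export
call_cells <- function(bundle, umi_floor = 500, fdr_threshold = NULL,
                       chemistry = NULL, strict_chemistries = character(),
                       n_simulations = 10000L, seed = 0L,
                       ambient_max = NULL, pseudocount = 0.5,
                       grid = NULL, grid_points = 2000L) {
  if (is.null(chemistry)) {
    chemistry <- bundle$log_meta$chemistry
    if (is.null(chemistry) || is.na(chemistry)) chemistry <- "unknown"
  }
  if (is.null(fdr_threshold))
    fdr_threshold <- if (chemistry %in% strict_chemistries) 0.001 else 0.01
  if (is.null(ambient_max)) ambient_max <- min(100, umi_floor / 5)

  ranking <- rank_barcodes(bundle)
  om <- ordmag_call(ranking, grid = grid, grid_points = grid_points)
  totals <- barcode_totals(bundle)
  is_ordmag <- logical(length(totals))
  is_ordmag[om$retained_indices] <- TRUE

  cand <- which(!is_ordmag & totals >= umi_floor)
  pool <- which(!is_ordmag & totals >= 1 & totals <= ambient_max)

  ed <- list(candidate_indices = integer(0), log_likelihoods = numeric(0),
             p_values = numeric(0), fdr = numeric(0),
             threshold_used = fdr_threshold,
             n_simulations = as.integer(n_simulations), seed = as.integer(seed))
  rescued <- integer(0)
  if (length(cand)) {
    if (!length(pool)) {
      warnf("no ambient pool barcodes (totals in [1, %g]); skipping the ambient rescue test", ambient_max)
    } else {
      profile <- estimate_ambient_profile(bundle, pool, pseudocount = pseudocount)
      cmat <- as.matrix(bundle$counts[cand, , drop = FALSE])
      ll <- apply(cmat, 1L, multinomial_loglik, profile = profile)
      pv <- montecarlo_pvalues(cmat, profile, n_simulations = n_simulations,
                               seed = seed)
      fdr <- bh_adjust(pv)
      ed$candidate_indices <- cand
      ed$log_likelihoods <- unname(ll)
      ed$p_values <- pv
      ed$fdr <- fdr
      rescued <- cand[fdr <= fdr_threshold]
    }
  }

  structure(list(
    ordmag = om,
    emptydrops = ed,
    retained = sort(union(om$retained_indices, rescued)),
    parameters = list(umi_floor = umi_floor, fdr_threshold = fdr_threshold,
                      chemistry = chemistry, ambient_max = ambient_max,
                      pseudocount = pseudocount,
                      n_simulations = as.integer(n_simulations),
                      seed = as.integer(seed),
                      grid_points = as.integer(grid_points),
                      ambient_pool_size = length(pool))
  ), class = "cell_calls")
}

#' @export
print.cell_calls <- function(x, ...) {
  cat(sprintf("cell_calls: %d retained (%d knee + %d rescued), FDR <= %g\n",
              length(x$retained), x$ordmag$expected_cells,
              length(x$retained) - x$ordmag$expected_cells,
              x$emptydrops$threshold_used))
  invisible(x)
}
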