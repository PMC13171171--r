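test_that("simulated doublets are exact parent sums with a shared gene axis", {
  m <- Matrix::Matrix(matrix(rpois(20 * 12, 5), 20, 12), sparse = TRUE)
  sim <- simulate_doublets(m, n_simulated = 30, seed = 1)
  expect_equal(ncol(sim$counts), ncol(m))
  expect_equal(nrow(sim$counts), 30)
  expect_true(all(sim$parents[, 1] != sim$parents[, 2]))
  # mass conservation, exactly
  expect_equal(Matrix::rowSums(sim$counts),
               Matrix::rowSums(m)[sim$parents[, 1]] +
                 Matrix::rowSums(m)[sim$parents[, 2]])
  # determinism
  sim2 <- simulate_doublets(m, n_simulated = 30, seed = 1)
  expect_identical(sim$parents, sim2$parents)
  expect_error(simulate_doublets(m[1, , drop = FALSE]), "at least 2")
})

test_that("doublet scores are finite fractions for a sweep of k", {
  sim <- simulate_experiment(synthetic_truth(
    n_true_cells = 40, n_populations = 2, n_ambient = 0, n_genes = 60,
    usa_fractions = NULL, seed = 17))
  m <- sim$bundle$counts
  for (k in c(1L, 5L, 15L, 25L)) {
    res <- suppressWarnings(doublet_scores(m, k = k, seed = 2))
    expect_true(all(is.finite(res$observed_scores)))
    expect_true(all(res$observed_scores >= 0 & res$observed_scores <= 1))
    expect_true(all(res$simulated_scores >= 0 & res$simulated_scores <= 1))
    expect_identical(res$is_doublet, res$observed_scores > res$threshold)
  }
  expect_error(doublet_scores(m, k = 1000L, seed = 2), "smaller")
})

test_that("identical cells give a unimodal score distribution and no flags", {
  m <- Matrix::Matrix(matrix(rep(c(5, 3, 2, 0, 1), each = 30), nrow = 30),
                      sparse = TRUE)
  expect_warning(res <- doublet_scores(m, k = 5, seed = 3), "not bimodal")
  expect_false(any(res$is_doublet))
  expect_equal(res$threshold, Inf)
})

test_that("planted hybrid cells score above threshold, pure cells below", {
  tr <- synthetic_truth(n_true_cells = 400L, n_populations = 2L,
                        doublet_rate = 0.05, n_ambient = 0L, n_genes = 300L,
                        usa_fractions = NULL, seed = 11)
  sim <- simulate_experiment(tr)
  is_hybrid <- seq_len(nrow(sim$bundle$counts)) %in% sim$truth$doublet_indices
  res <- doublet_scores(sim$bundle$counts, seed = 11)
  expect_gte(mean(res$is_doublet[is_hybrid]), 0.8)   # recall
  expect_lte(mean(res$is_doublet[!is_hybrid]), 0.1)  # false-positive rate
})

test_that("embedding skips degenerate inputs with a warning, never an error", {
  small <- Matrix::Matrix(matrix(rpois(10 * 8, 4), 10, 8), sparse = TRUE)
  expect_warning(out <- embed_cells(small), "skipping")
  expect_null(out)
  onegene <- Matrix::Matrix(cbind(rpois(40, 5), rep(0, 40)), sparse = TRUE)
  expect_warning(out2 <- embed_cells(onegene, min_cells = 10), "skipping")
  expect_null(out2)
})

test_that("embeddings are deterministic, sized to the kept cells, and separate planted populations", {
  sim <- simulate_experiment(synthetic_truth(
    n_true_cells = 80L, n_populations = 2L, n_ambient = 0L, n_genes = 120L,
    usa_fractions = NULL, seed = 5))
  m <- sim$bundle$counts
  emb <- embed_cells(m, seed = 5)
  expect_equal(nrow(emb$coordinates_umap), 80)
  expect_equal(nrow(emb$coordinates_tsne), 80)
  emb2 <- embed_cells(m, seed = 5)
  expect_identical(emb$coordinates_umap, emb2$coordinates_umap)
  expect_identical(emb$coordinates_tsne, emb2$coordinates_tsne)

  pop <- integer(nrow(m)); pop[sim$truth$cell_indices] <- sim$truth$population
  for (nm in c("coordinates_umap", "coordinates_tsne")) {
    d <- as.matrix(stats::dist(emb[[nm]]))
    same <- outer(pop, pop, "==")
    diag(same) <- NA
    expect_gt(mean(d[!same & !is.na(same)]), mean(d[same & !is.na(same)]))
  }

  # doublet exclusion changes the output row count accordingly
  fake <- structure(list(is_doublet = c(rep(TRUE, 5), rep(FALSE, 75))),
                    class = "doublet_result")
  emb3 <- embed_cells(m, doublets = fake, exclude_doublets = TRUE, seed = 5)
  expect_equal(nrow(emb3$coordinates_umap), 75)
  expect_equal(sum(emb3$cell_mask), 75)
})
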