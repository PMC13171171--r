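test_that("simulation is deterministic given the seed and leaves the RNG alone", {
  tr <- synthetic_truth(n_true_cells = 15, n_ambient = 30, n_genes = 20,
                        seed = 12)
  set.seed(99); before <- stats::runif(1)
  set.seed(99)
  a <- simulate_experiment(tr)
  expect_equal(stats::runif(1), before)   # caller RNG untouched
  b <- simulate_experiment(tr)
  expect_equal(as.matrix(a$bundle$counts), as.matrix(b$bundle$counts),
               ignore_attr = TRUE)
  expect_identical(a$truth$cell_indices, b$truth$cell_indices)
})

test_that("with zero ambient barcodes every barcode is a planted cell", {
  sim <- simulate_experiment(synthetic_truth(
    n_true_cells = 12, n_ambient = 0, n_genes = 20, seed = 13))
  expect_equal(nrow(sim$bundle$counts), 12)
  expect_setequal(sim$truth$cell_indices, 1:12)
})

test_that("layer totals reproduce the planted splice fractions within sampling error", {
  fr <- c(0.6, 0.25, 0.15)
  sim <- simulate_experiment(synthetic_truth(
    n_true_cells = 50, n_ambient = 200, n_genes = 60,
    usa_fractions = fr, seed = 14))
  b <- sim$bundle
  n <- sum(b$counts)
  obs <- c(sum(b$layer_S), sum(b$layer_U), sum(b$layer_A)) / n
  # binomial 99.9% CI half-width at the planted n, per component
  hw <- 3.29 * sqrt(fr * (1 - fr) / n)
  expect_true(all(abs(obs - fr) <= hw))
  # nuclei preset shifts mass to unspliced
  nuc <- simulate_experiment(synthetic_truth(
    n_true_cells = 50, n_ambient = 200, n_genes = 60,
    usa_fractions = c(0.15, 0.75, 0.10), seed = 14))
  expect_gt(sum(nuc$bundle$layer_U) / sum(nuc$bundle$counts), 0.6)
})

test_that("fixture directories round-trip through the loader", {
  sim <- simulate_experiment(synthetic_truth(
    n_true_cells = 20, n_ambient = 50, n_genes = 30, seed = 15))
  d <- tempfile()
  on.exit(unlink(d, recursive = TRUE))
  write_fixture_dir(sim$bundle, d, truth = sim$truth)
  b <- load_quant_dir(d)
  expect_true(has_usa_layers(b))       # USA auto-detected
  expect_equal(as.matrix(b$counts), as.matrix(sim$bundle$counts),
               ignore_attr = TRUE)
  expect_identical(b$barcodes, sim$bundle$barcodes)
  expect_true(file.exists(file.path(d, "synthetic_truth.json")))
})

test_that("planted log quantities are reproduced by the parser", {
  tr <- synthetic_truth(n_true_cells = 20, n_ambient = 50, n_genes = 30,
                        mapping_rate = 0.85, saturation = 0.3, seed = 16)
  sim <- simulate_experiment(tr)
  d <- tempfile()
  on.exit(unlink(d, recursive = TRUE))
  write_fixture_dir(sim$bundle, d)
  lm <- parse_logs(d)
  expect_equal(lm$num_mapped_reads / lm$num_processed_reads, 0.85,
               tolerance = 1e-3)
  expect_equal(sequencing_saturation(lm$num_mapped_reads,
                                     sum(sim$bundle$counts)),
               0.3, tolerance = 1e-3)
  expect_equal(lm$chemistry, "10xv3")
})

test_that("infeasible parameters error early", {
  expect_error(synthetic_truth(n_genes = 1), "at least 2 genes")
  expect_error(synthetic_truth(usa_fractions = c(0.5, 0.5)), "simplex")
})
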