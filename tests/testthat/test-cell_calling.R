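test_that("barcode ranking sorts descending, stably, and rejects all-zero input", {
  r <- rank_barcodes(c(5, 9, 1))
  expect_equal(r$counts, c(9, 5, 1))
  expect_equal(r$order, c(2, 1, 3))

  r2 <- rank_barcodes(c(7, 7))
  expect_equal(r2$order, c(1, 2))  # ties keep original order

  expect_error(rank_barcodes(c(0, 0)), "no counted barcodes")
})

test_that("the 99th percentile uses linear interpolation between order statistics", {
  expect_equal(percentile99(rep(1000, 100)), 1000)
  expect_equal(percentile99(42), 42)
  expect_equal(percentile99(1:100), 99.01)
  expect_error(percentile99(numeric(0)), "empty")
  # property: matches the standard type-7 quantile on random inputs
  for (seed in 1:20) {
    x <- withr_seed(seed, stats::rpois(sample(2:60, 1), 50))
    expect_equal(percentile99(x),
                 unname(stats::quantile(x, 0.99, type = 7)))
  }
})

test_that("observed cell count applies the strict dynamic cutoff", {
  r <- rank_barcodes(c(100, 90, 10, 9, 1))
  expect_equal(observed_cell_count(r, 100), 2)   # cutoff 10, strict
  expect_equal(observed_cell_count(r, 89), 4)    # cutoff 8.9; 9 > 8.9 counts
  expect_equal(observed_cell_count(r, 0), 5)     # all nonzero
  expect_error(observed_cell_count(r, -1), "non-negative")
})

test_that("the knee loss is (obs - cand)^2 / cand", {
  expect_equal(ordmag_loss(100, 100), 0)
  expect_equal(ordmag_loss(0, 100), 100)
  expect_equal(ordmag_loss(150, 100), 25)
  expect_error(ordmag_loss(10, 0), ">= 1")
})

test_that("knee estimation recovers a clean bimodal population", {
  totals <- c(rep(1000, 100), rep(10, 900))
  r <- rank_barcodes(totals)
  om <- ordmag_call(r)
  # independent literal re-evaluation of the same candidate list
  orc <- oracle_ordmag(totals, om$candidates)
  expect_equal(om$losses, orc$losses, tolerance = 1e-12)
  expect_equal(om$m_k, orc$m_k, tolerance = 1e-12)
  expect_equal(om$observed, orc$observed)
  expect_identical(om$expected_cells, orc$expected_cells)
  expect_equal(om$expected_cells, 100)
  expect_setequal(om$retained_indices, 1:100)
})

test_that("a single equal-count population is retained in full", {
  totals <- rep(800, 40)
  om <- ordmag_call(rank_barcodes(totals))
  expect_equal(om$expected_cells, 40)
  orc <- oracle_ordmag(totals, om$candidates)
  expect_identical(om$expected_cells, orc$expected_cells)
})

test_that("a singleton grid at the true count matches the full grid", {
  totals <- c(rep(1000, 100), rep(10, 900))
  r <- rank_barcodes(totals)
  full <- ordmag_call(r)
  single <- ordmag_call(r, grid = 100, refine = FALSE)
  expect_equal(single$expected_cells, full$expected_cells)
  expect_setequal(single$retained_indices, full$retained_indices)
  expect_error(ordmag_call(r, grid = 1e6), "empty")
})

test_that("knee retention is always a prefix of the descending ranking", {
  for (seed in 1:5) {
    sim <- simulate_experiment(synthetic_truth(
      n_true_cells = 60, n_ambient = 400, n_genes = 80, seed = seed))
    r <- rank_barcodes(sim$bundle)
    om <- ordmag_call(r)
    expect_identical(om$retained_indices,
                     r$order[seq_len(om$expected_cells)])
  }
})

test_that("the ambient profile is a smoothed normalized pool", {
  b <- quant_bundle(Matrix::Matrix(matrix(c(9, 0, 1, 0), 2, 2), sparse = TRUE),
                    barcodes = c("b1", "b2"), genes = c("g1", "g2"))
  expect_equal(estimate_ambient_profile(b, 1:2, pseudocount = 0),
               c(0.9, 0.1))
  b2 <- quant_bundle(Matrix::Matrix(matrix(c(0, 0, 10), 1, 3), sparse = TRUE),
                     barcodes = "b1", genes = c("g1", "g2", "g3"))
  expect_equal(estimate_ambient_profile(b2, 1, pseudocount = 0.5),
               c(0.5, 0.5, 10.5) / 11.5)
  expect_error(estimate_ambient_profile(b, integer(0)), "empty pool")
  # normalization invariant on random pools
  for (seed in 1:5) {
    sim <- simulate_experiment(synthetic_truth(
      n_true_cells = 10, n_ambient = 40, n_genes = 25, seed = seed))
    p <- estimate_ambient_profile(sim$bundle, sample(1:50, 20))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
  }
})

test_that("the multinomial log-likelihood matches closed forms and normalizes", {
  expect_equal(multinomial_loglik(c(1, 0), c(0.9, 0.1)), log(0.9))
  expect_equal(multinomial_loglik(c(1, 1), c(0.5, 0.5)), log(0.5))
  expect_error(multinomial_loglik(c(1, 0, 0), c(0.5, 0.5)), "lengths differ")
  # exhaustive normalization: total = 3 over 2 genes, 4 outcomes sum to 1
  outcomes <- enumerate_2gene(3)
  for (prof in list(c(0.5, 0.5), c(0.3, 0.7))) {
    tot <- sum(exp(apply(outcomes, 1, multinomial_loglik, profile = prof)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("Monte-Carlo p-values behave at the estimator boundary and under permutation", {
  prof <- c(0.5, 0.3, 0.2)
  # a candidate far less likely than any plausible draw: p = 1/(n+1)
  cand <- rbind(c(0, 0, 50), c(25, 15, 10))
  p <- montecarlo_pvalues(cand, prof, n_simulations = 200, seed = 42)
  expect_equal(p[1], 1 / 201)
  # permuting candidates permutes p-values identically at the same seed
  p_rev <- montecarlo_pvalues(cand[2:1, ], prof, n_simulations = 200, seed = 42)
  expect_equal(p_rev, p[2:1])
  expect_true(all(p > 0 & p <= 1))
  expect_error(montecarlo_pvalues(cand, prof, n_simulations = 0), ">= 1")
})

test_that("BH adjustment matches the literal step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.05, 4)), rep(0.05, 4))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
  for (seed in 1:10) {
    p <- withr_seed(seed, stats::runif(sample(1:40, 1)))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("cell calling with no mid-range barcodes retains exactly the knee set", {
  fx <- make_rescue_bundle(n_high = 50, n_low = 400, seed = 3)
  calls <- call_cells(fx$bundle, n_simulations = 500, seed = 1)
  expect_length(calls$emptydrops$candidate_indices, 0)
  expect_setequal(calls$retained, calls$ordmag$retained_indices)
})

test_that("planted mid-range real cells are rescued; ambient ones are not", {
  fx <- make_rescue_bundle(n_high = 50, n_low = 400,
                           n_mid_real = 20, n_mid_amb = 20, seed = 5)
  calls <- call_cells(fx$bundle, n_simulations = 2000, seed = 1)
  expect_equal(sort(calls$ordmag$retained_indices), which(fx$labels == "high"))
  mid_real <- which(fx$labels == "mid_real")
  mid_amb <- which(fx$labels == "mid_amb")
  expect_true(all(mid_real %in% calls$retained))       # full power here
  expect_lte(mean(mid_amb %in% calls$retained), 0.1)   # type-I control
  # the calling rule holds exactly
  ed <- calls$emptydrops
  rescued <- ed$candidate_indices[ed$fdr <= ed$threshold_used]
  expect_setequal(calls$retained,
                  union(calls$ordmag$retained_indices, rescued))
})

test_that("a umi_floor above every candidate total collapses calling to the knee set", {
  fx <- make_rescue_bundle(n_high = 50, n_low = 400,
                           n_mid_real = 10, n_mid_amb = 0, seed = 7)
  calls <- call_cells(fx$bundle, umi_floor = 10000 + 200,
                      n_simulations = 200, seed = 1)
  expect_length(calls$emptydrops$candidate_indices, 0)
  expect_setequal(calls$retained, calls$ordmag$retained_indices)
})

test_that("raising the FDR threshold never shrinks the retained set", {
  fx <- make_rescue_bundle(n_high = 50, n_low = 400,
                           n_mid_real = 15, n_mid_amb = 15, seed = 9)
  strict <- call_cells(fx$bundle, fdr_threshold = 0.001,
                       n_simulations = 2000, seed = 1)
  loose <- call_cells(fx$bundle, fdr_threshold = 0.01,
                      n_simulations = 2000, seed = 1)
  expect_true(all(strict$retained %in% loose$retained))
})

test_that("the chemistry rule selects the configured strict threshold", {
  fx <- make_rescue_bundle(n_high = 30, n_low = 200, seed = 2)
  c1 <- call_cells(fx$bundle, n_simulations = 100, seed = 1)
  expect_equal(c1$emptydrops$threshold_used, 0.01)
  c2 <- call_cells(fx$bundle, chemistry = "chemX",
                   strict_chemistries = "chemX",
                   n_simulations = 100, seed = 1)
  expect_equal(c2$emptydrops$threshold_used, 0.001)
})
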