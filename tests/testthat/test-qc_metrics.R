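test_that("sequencing saturation follows 1 - UMIs/reads with the zero convention", {
  expect_equal(sequencing_saturation(100, 100), 0)
  expect_equal(sequencing_saturation(100, 50), 0.5)
  expect_equal(sequencing_saturation(0, 0), 0)
  expect_error(sequencing_saturation(50, 100), "more unique UMIs")
  # duplicating reads (same UMIs) strictly increases saturation
  expect_gt(sequencing_saturation(200, 80), sequencing_saturation(100, 80))
})

test_that("spliced ratio groups ambiguous with spliced and handles zero totals", {
  expect_equal(spliced_ratio(10, 0, 0), 1)
  expect_equal(spliced_ratio(0, 10, 0), 0)
  expect_equal(spliced_ratio(5, 5, 0), 0.5)
  expect_true(is.na(spliced_ratio(0, 0, 0)))
  # dataset-level ratio equals the (S+U+A)-weighted mean of per-cell ratios
  sim <- simulate_experiment(synthetic_truth(
    n_true_cells = 30, n_ambient = 100, n_genes = 40, seed = 4))
  b <- sim$bundle
  S <- Matrix::rowSums(b$layer_S); U <- Matrix::rowSums(b$layer_U)
  A <- Matrix::rowSums(b$layer_A)
  per <- spliced_ratio(S, U, A)
  w <- S + U + A
  expect_equal(sum(per * w, na.rm = TRUE) / sum(w[!is.na(per)]),
               spliced_ratio(sum(S), sum(U), sum(A)))
  expect_true(all(per[!is.na(per)] >= 0 & per[!is.na(per)] <= 1))
})

test_that("mitochondrial fractions come from symbol prefixes and never filter", {
  m <- Matrix::Matrix(matrix(c(9, 0, 1, 10), 2, 2), sparse = TRUE)
  b <- quant_bundle(m, barcodes = c("b1", "b2"), genes = c("g1", "g2"),
                    gene_symbols = c("ACTB", "MT-CO1"))
  expect_equal(mito_fraction(b), c(1 / 10, 1))
  b2 <- quant_bundle(m, barcodes = c("b1", "b2"), genes = c("g1", "g2"),
                     gene_symbols = c("ACTB", "GAPDH"))
  expect_equal(mito_fraction(b2), c(0, 0))
  # explicit list overrides prefix detection
  expect_equal(mito_fraction(b2, mito_gene_mask(b2, mito_genes = "g1")),
               c(9 / 10, 0))
  # all counts on mito genes
  b3 <- quant_bundle(m, barcodes = c("b1", "b2"), genes = c("g1", "g2"),
                     gene_symbols = c("MT-CO1", "MT-ND1"))
  expect_equal(mito_fraction(b3), c(1, 1))
})

test_that("knee curves compress plateaus without losing endpoints", {
  k <- knee_curve(c(100, 100, 10))
  expect_equal(k$rank, c(1, 2, 3))
  expect_equal(k$value, c(100, 100, 10))

  dec <- c(50, 40, 30, 20, 10)
  expect_equal(knee_curve(dec)$value, dec)

  k2 <- knee_curve(c(rep(1000, 10), rep(5, 8), 0, 0))
  expect_equal(k2$rank, c(1, 10, 11, 18))   # plateau endpoints only
  expect_equal(max(k2$value), 1000)
  expect_equal(min(k2$value), 5)            # zeros dropped
  expect_error(knee_curve(numeric(0)), "empty")
})

test_that("summary statistics are computed over retained cells with log-derived rates", {
  m <- Matrix::Matrix(rbind(c(8, 2, 0), c(25, 5, 0), c(1, 0, 0)), sparse = TRUE)
  b <- quant_bundle(m, barcodes = paste0("b", 1:3), genes = paste0("g", 1:3),
                    log_meta = log_summary(num_processed_reads = 1000,
                                           num_mapped_reads = 900,
                                           num_processed_barcodes = 3))
  calls <- list(retained = c(1L, 2L),
                ordmag = list(retained_indices = c(1L, 2L)),
                emptydrops = list(candidate_indices = integer(0)))
  qc <- summarize_qc(b, calls)
  expect_equal(qc$n_retained_cells, 2)
  expect_equal(qc$n_processed_barcodes, 3)
  expect_equal(qc$median_umis_per_cell, 20)        # median of {10, 30}
  expect_equal(qc$median_genes_per_cell, 2)
  expect_equal(qc$mean_reads_per_cell, 500)
  expect_equal(qc$mapping_rate, 0.9)
  expect_equal(qc$sequencing_saturation, 1 - 41 / 900)
  # direct column-scan oracle for the gene support of retained cells
  expect_equal(qc$total_genes_detected,
               sum(colSums(as.matrix(m[1:2, ])) > 0))
})

test_that("absent logs leave read-derived metrics absent, matrix metrics present", {
  m <- Matrix::Matrix(rbind(c(8, 2), c(25, 5)), sparse = TRUE)
  b <- quant_bundle(m, barcodes = c("b1", "b2"), genes = c("g1", "g2"))
  calls <- list(retained = c(1L, 2L))
  qc <- summarize_qc(b, calls)
  expect_true(is.na(qc$mean_reads_per_cell))
  expect_true(is.na(qc$mapping_rate))
  expect_true(is.na(qc$sequencing_saturation))
  expect_equal(qc$median_umis_per_cell, 20)
})

test_that("zero retained cells yields absent medians with a prominent warning", {
  m <- Matrix::Matrix(rbind(c(8, 2), c(25, 5)), sparse = TRUE)
  b <- quant_bundle(m, barcodes = c("b1", "b2"), genes = c("g1", "g2"))
  expect_warning(qc <- summarize_qc(b, list(retained = integer(0))),
                 "zero retained")
  expect_true(is.na(qc$median_umis_per_cell))
  expect_equal(qc$n_retained_cells, 0)
})

test_that("the per-barcode table carries ranks, ratios and calling columns", {
  sim <- simulate_experiment(synthetic_truth(
    n_true_cells = 20, n_ambient = 60, n_genes = 30, seed = 6))
  calls <- call_cells(sim$bundle, n_simulations = 100, seed = 1)
  tab <- per_barcode_qc(sim$bundle, calls)
  expect_equal(nrow(tab), 80)
  expect_equal(tab$total_umis, barcode_totals(sim$bundle))
  expect_setequal(tab$rank, 1:80)
  expect_equal(sum(tab$retained), length(calls$retained))
  expect_equal(which(tab$ordmag_retained),
               sort(calls$ordmag$retained_indices))
  expect_true(all(tab$spliced_ratio >= 0 & tab$spliced_ratio <= 1,
                  na.rm = TRUE))
})
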