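# Synthetic droplet experiments with planted ground truth: high-depth true
# cells over a distinct expression program, low-depth ambient barcodes from
# a background profile, optional doublets and splice-status (S/U/A) layers,
# plus consistent step logs. Every other module is testable against the
# planted truth without any external download.

#' Parameters of a synthetic droplet experiment
#'
#' Defaults describe a clean small experiment: 100 true cells with
#' log-normal depths around 2000 UMIs (sdlog 0.3), 2000 ambient barcodes
#' with uniform-log depths in [1, 100] (a >=20x depth separation producing
#' the sharp knee of healthy data), splice fractions (S, U, A) =
#' (0.60, 0.25, 0.15) typical of whole cells. Use
#' `usa_fractions = c(0.15, 0.75, 0.10)` for a nuclei-like preset where
#' unspliced counts dominate.
#'
#' @param n_true_cells number of planted true cells.
#' @param n_ambient number of ambient (empty-droplet) barcodes.
#' @param n_genes gene count.
#' @param cell_depth_meanlog,cell_depth_sdlog log-normal UMI-depth
#'   parameters for true cells.
#' @param ambient_depth_range two-element range of ambient depths, sampled
#'   uniformly on the log scale.
#' @param n_populations number of distinct cell populations (equal mix).
#' @param doublet_rate fraction of extra barcodes planted as doublets
#'   (pairwise sums of two true-cell draws).
#' @param usa_fractions length-3 simplex point (S, U, A); `NULL` disables
#'   splice layers.
#' @param n_mito number of genes labelled mitochondrial (symbol `MT-*`).
#' @param mapping_rate,saturation planted log-file quantities.
#' @param chemistry chemistry tag written into the logs.
#' @param seed RNG seed; the whole experiment is deterministic given it.
#' @return object of class `synthetic_truth` (also carries the planted
#'   per-barcode assignments after [simulate_experiment()]).
#' @export
synthetic_truth <- function(n_true_cells = 100L, n_ambient = 2000L,
                            n_genes = 200L,
                            cell_depth_meanlog = log(2000),
                            cell_depth_sdlog = 0.3,
                            ambient_depth_range = c(1, 100),
                            n_populations = 1L, doublet_rate = 0,
                            usa_fractions = c(S = 0.60, U = 0.25, A = 0.15),
                            n_mito = 5L, mapping_rate = 0.87,
                            saturation = 0.4, chemistry = "10xv3",
                            seed = 0L) {
  if (n_genes < 2L) stopf("need at least 2 genes")
  if (!is.null(usa_fractions)) {
    if (length(usa_fractions) != 3L || any(usa_fractions < 0) ||
        abs(sum(usa_fractions) - 1) > 1e-8)
      stopf("usa_fractions must be a length-3 simplex point")
  }
  structure(list(
    n_true_cells = as.integer(n_true_cells), n_ambient = as.integer(n_ambient),
    n_genes = as.integer(n_genes),
    cell_depth_meanlog = cell_depth_meanlog, cell_depth_sdlog = cell_depth_sdlog,
    ambient_depth_range = ambient_depth_range,
    n_populations = as.integer(n_populations), doublet_rate = doublet_rate,
    usa_fractions = usa_fractions, n_mito = as.integer(n_mito),
    mapping_rate = mapping_rate, saturation = saturation,
    chemistry = chemistry, seed = as.integer(seed)
  ), class = "synthetic_truth")
}

# population expression programs: shared baseline plus a population-private
# block of up-weighted genes, so populations are well separated in PC space
make_profiles <- function(n_genes, n_populations) {
  block <- max(2L, n_genes %/% (2L * max(n_populations, 1L)))
  profs <- matrix(stats::rgamma(n_genes * n_populations, shape = 1),
                  nrow = n_populations)
  for (p in seq_len(n_populations)) {
    idx <- ((p - 1L) * block + 1L):(p * block)
    profs[p, idx] <- profs[p, idx] + 20
  }
  profs / rowSums(profs)
}

split_usa <- function(mat, fr) {
  x <- mat@x
  s <- stats::rbinom(length(x), x, fr[1])
  rem <- x - s
  pu <- if (fr[2] + fr[3] > 0) fr[2] / (fr[2] + fr[3]) else 0
  u <- stats::rbinom(length(x), rem, pu)
  a <- rem - u
  build <- function(v) {
    out <- mat
    out@x <- as.numeric(v)
    Matrix::drop0(out)
  }
  list(S = build(s), U = build(u), A = build(a))
}

#' Simulate a droplet experiment with planted truth
#'
#' True cells draw their depths from the log-normal depth distribution and
#' their gene vectors multinomially from their population's program;
#' ambient barcodes draw low uniform-log depths from the ambient profile;
#' doublets are sums of two true-cell draws; per-UMI splice statuses drawn
#' from `usa_fractions` produce the S/U/A layers. Consistent step logs are
#' planted from `mapping_rate` and `saturation`. Deterministic given
#' `truth$seed`.
#'
#' @param truth a [synthetic_truth()].
#' @return list with `bundle` (a [quant_bundle()]) and `truth`, the input
#'   augmented with `cell_indices`, `ambient_indices`, `doublet_indices`,
#'   `population` (per true cell), `doublet_pairs`,
#'   `cell_expression_profile`, `ambient_profile`, `mito_gene_indices`.
#' @export
simulate_experiment <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_seed(truth$seed, {
    ng <- truth$n_genes
    profs <- make_profiles(ng, truth$n_populations)
    # ambient profile: flatter background, distinct from every program
    ambient <- stats::rgamma(ng, shape = 2) + 0.5
    ambient <- ambient / sum(ambient)

    nc <- truth$n_true_cells
    pop <- rep_len(seq_len(truth$n_populations), nc)
    depths <- pmax(1, round(stats::rlnorm(nc, truth$cell_depth_meanlog,
                                          truth$cell_depth_sdlog)))
    cells <- vapply(seq_len(nc), function(i)
      stats::rmultinom(1, depths[i], profs[pop[i], ])[, 1], numeric(ng))

    nd <- round(truth$doublet_rate * nc)
    doublet_pairs <- NULL
    doublets <- NULL
    if (nd > 0) {
      doublet_pairs <- cbind(sample.int(nc, nd, replace = TRUE),
                             sample.int(nc, nd, replace = TRUE))
      # force cross-population pairs when possible for hybrid profiles
      if (truth$n_populations > 1L) {
        for (j in seq_len(nd)) {
          tries <- 0L
          while (pop[doublet_pairs[j, 1]] == pop[doublet_pairs[j, 2]] &&
                 tries < 50L) {
            doublet_pairs[j, 2] <- sample.int(nc, 1L)
            tries <- tries + 1L
          }
        }
      }
      doublets <- cells[, doublet_pairs[, 1], drop = FALSE] +
        cells[, doublet_pairs[, 2], drop = FALSE]
    }

    na <- truth$n_ambient
    amb <- NULL
    if (na > 0) {
      lr <- log(truth$ambient_depth_range)
      adep <- pmax(1, round(exp(stats::runif(na, lr[1], lr[2]))))
      amb <- vapply(seq_len(na), function(i)
        stats::rmultinom(1, adep[i], ambient)[, 1], numeric(ng))
    }

    mat <- t(cbind(cells, doublets, amb))  # barcodes x genes
    n_all <- nrow(mat)
    perm <- sample.int(n_all)              # shuffle barcode order
    mat <- mat[perm, , drop = FALSE]
    where <- integer(n_all); where[perm] <- seq_len(n_all)

    barcodes <- sprintf("BC%06d", seq_len(n_all))
    genes <- sprintf("G%04d", seq_len(ng))
    mito_idx <- if (truth$n_mito > 0) seq_len(min(truth$n_mito, ng)) else integer(0)
    symbols <- sprintf("GENE%04d", seq_len(ng))
    symbols[mito_idx] <- sprintf("MT-%04d", seq_along(mito_idx))

    smat <- as_dgc(mat)
    layers <- if (!is.null(truth$usa_fractions))
      split_usa(smat, truth$usa_fractions) else NULL

    total_umis <- sum(smat)
    n_mapped <- ceiling(total_umis / (1 - truth$saturation))
    n_processed <- round(n_mapped / truth$mapping_rate)
    logs <- log_summary(
      num_processed_reads = n_processed, num_mapped_reads = n_mapped,
      num_processed_barcodes = n_all, chemistry = truth$chemistry,
      raw_log_tables = list())

    bundle <- if (is.null(layers)) {
      quant_bundle(counts = smat, barcodes = barcodes, genes = genes,
                   gene_symbols = symbols, log_meta = logs)
    } else {
      quant_bundle(barcodes = barcodes, genes = genes, gene_symbols = symbols,
                   layer_S = layers$S, layer_U = layers$U, layer_A = layers$A,
                   log_meta = logs)
    }

    truth$cell_indices <- where[seq_len(nc)]
    truth$doublet_indices <- if (nd > 0) where[nc + seq_len(nd)] else integer(0)
    truth$ambient_indices <- if (na > 0) where[nc + nd + seq_len(na)] else integer(0)
    truth$population <- pop
    truth$doublet_pairs <- doublet_pairs
    truth$cell_expression_profile <- profs
    truth$ambient_profile <- ambient
    truth$mito_gene_indices <- mito_idx
    truth$planted_logs <- list(num_processed_reads = n_processed,
                               num_mapped_reads = n_mapped)
    list(bundle = bundle, truth = truth)
  })
}

#' Write a synthetic quantification directory
#'
#' Lays the bundle out the way the loader expects a quantification output:
#' a MatrixMarket matrix (S/U/A layers expanded to suffixed feature blocks
#' when present), barcode and feature lists, and JSON logs for the
#' quantification and permit-list steps consistent with the bundle's
#' metadata. The planted truth, when given, is saved as
#' `synthetic_truth.json` for test harnesses.
#'
#' @param bundle a [quant_bundle()].
#' @param path output directory (created).
#' @param truth optional [synthetic_truth()] to save alongside.
#' @return `path`, invisibly.
#' @export
write_fixture_dir <- function(bundle, path, truth = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  usa <- has_usa_layers(bundle)
  if (usa) {
    mat <- cbind(bundle$layer_S, bundle$layer_U, bundle$layer_A)
    features <- c(bundle$genes, paste0(bundle$genes, "-U"),
                  paste0(bundle$genes, "-A"))
    symbols <- if (!is.null(bundle$gene_symbols))
      c(bundle$gene_symbols, paste0(bundle$gene_symbols, "-U"),
        paste0(bundle$gene_symbols, "-A")) else NULL
  } else {
    mat <- bundle$counts
    features <- bundle$genes
    symbols <- bundle$gene_symbols
  }
  Matrix::writeMM(as_dgc(mat), file.path(path, "quants_mat.mtx"))
  writeLines(bundle$barcodes, file.path(path, "quants_mat_rows.txt"))
  flines <- if (is.null(symbols)) features else paste(features, symbols, sep = "\t")
  writeLines(flines, file.path(path, "quants_mat_cols.txt"))

  lm <- bundle$log_meta
  jw <- function(x, f) jsonlite::write_json(x, file.path(path, f),
                                            auto_unbox = TRUE, digits = NA)
  quant_log <- list(num_processed = lm$num_processed_reads,
                    num_mapped = lm$num_mapped_reads,
                    chemistry = lm$chemistry,
                    quant_version = "synthetic-0.1")
  quant_log <- quant_log[!vapply(quant_log, function(v)
    is.null(v) || (length(v) == 1 && is.na(v)), logical(1))]
  if (length(quant_log)) jw(quant_log, "quant.json")
  permit_log <- list(num_barcodes = lm$num_processed_barcodes,
                     permit_list_version = "synthetic-0.1",
                     cmd = "umiqc simulate")
  permit_log <- permit_log[!vapply(permit_log, function(v)
    is.null(v) || (length(v) == 1 && is.na(v)), logical(1))]
  if (length(permit_log)) jw(permit_log, "generate_permit_list.json")

  if (!is.null(truth)) {
    tr <- unclass(truth)
    tr$cell_expression_profile <- NULL  # bulky; regenerate from seed instead
    tr$ambient_profile <- NULL
    jw(tr, "synthetic_truth.json")
  }
  invisible(path)
}
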