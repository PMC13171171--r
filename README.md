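# umiqc

Quality control and cell calling for UMI-based single-cell
quantification results.

Droplet-based single-cell experiments capture many more barcodes than
cells: most droplets hold only ambient RNA. `umiqc` takes a
quantification output directory (sparse MatrixMarket counts, barcode and
feature lists, JSON step logs — including splice-aware output where
spliced/unspliced/ambiguous UMI counts are reported per gene) or an
annotated-matrix HDF5 file, and

* **calls cells** with a two-stage algorithm:
  1. *order-of-magnitude knee estimation* — for a candidate cell number
     $c$, take the 99th-percentile UMI count $m$ of the top-$c$
     barcodes, count the barcodes with totals above $m/10$, and pick the
     $c$ minimizing $L(c) = (c^o - c)^2 / c$; the top $c^\ast$ barcodes
     are retained outright;
  2. *ambient-multinomial rescue* — every other barcode with ≥ 500 UMIs
     is tested against the ambient profile (pooled low-count droplets,
     pseudocount-smoothed) with a seeded Monte-Carlo multinomial test;
     Benjamini–Hochberg-adjusted p-values at or below the FDR threshold
     (0.01, or 0.001 for configured chemistries) add the barcode to the
     retained set;
* **computes QC statistics**: retained/processed counts, mean reads and
  median UMIs/genes per cell, sequencing saturation
  $1 - \mathrm{UMIs}/\mathrm{mapped\ reads}$, mapping rate, per-cell
  spliced ratio $(S+A)/(S+U+A)$ and mitochondrial fraction (reported,
  never used to filter);
* **scores doublets** from simulated cell-pair sums via a kNN
  neighbourhood fraction with automatic bimodal thresholding, and embeds
  retained cells with UMAP/t-SNE;
* **renders a self-contained HTML report** (summary, knee plots, splice
  composition, mitochondrial content, log tables; unavailable sections
  are marked skipped, never break the report);
* **exports an annotated HDF5 matrix** (H5AD-compatible, via the
  bundled `anndata` helper) carrying counts, layers, per-barcode calling
  columns and all metadata;
* ships a **synthetic experiment generator** with planted ground truth
  (true cells, ambient barcodes, doublet pairs, splice fractions,
  consistent logs) so the whole pipeline is testable offline.

## Worked example

```r
library(umiqc)

truth <- synthetic_truth(seed = 7)        # 100 cells, 2000 ambient barcodes
sim <- simulate_experiment(truth)
dir <- tempfile()
write_fixture_dir(sim$bundle, dir, truth = sim$truth)

bundle <- load_quant_dir(dir)             # auto-detects the S/U/A layers
calls <- call_cells(bundle, n_simulations = 2000)
calls
#> cell_calls: 100 retained (100 knee + 0 rescued), FDR <= 0.01
setequal(calls$retained, sim$truth$cell_indices)
#> [1] TRUE

summarize_qc(bundle, calls)
#> QC summary
#>   retained cells:         100
#>   processed barcodes:     2,100
#>   mean reads / cell:      4,677.8
#>   median UMIs / cell:     1,885
#>   median genes / cell:    148
#>   total genes detected:   200
#>   sequencing saturation:  40.0%
#>   mapping rate:           87.0%
```

All 100 planted cells — and nothing else — are retained; the saturation
and mapping rate recover the values planted in the synthetic logs (40%
and 87%). The one-shot pipeline (report + annotated matrix) is

```r
res <- run_pipeline(dir, "qc_out")        # writes qc_out/qc_report.html
                                          # and qc_out/quants_annotated.h5ad
```

or, from the shell (see also `umiqc simulate`):

```sh
Rscript -e 'umiqc::umiqc_main()' run --input <quant_dir> --output qc_out
```

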