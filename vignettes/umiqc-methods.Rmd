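---
title: "Methods: cell calling and quality control for UMI-based single-cell quantification"
author: "umiqc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell calling and quality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`umiqc` post-processes UMI-based single-cell quantification output: it
loads a quantification directory (sparse MatrixMarket counts, barcode and
feature lists, JSON step logs) or an annotated-matrix HDF5 file,
distinguishes real cells from empty droplets, computes the standard QC
statistics, optionally scores doublets and embeds cells in 2-D, renders a
self-contained HTML report, and exports an annotated HDF5 matrix. It does
not run quantification itself, and it never filters cells on
mitochondrial content — that statistic is stored for the user's own
judgement.

Splice-aware quantification reports spliced (S), unspliced (U) and
ambiguous (A) UMI counts per gene as three feature blocks (`g`, `g-U`,
`g-A`). The loader auto-detects this convention (at least one `-U`
feature, and stripping the suffixes collapses the feature set three-fold),
collapses the blocks onto one gene axis, keeps the three layers, and
defines the working count matrix as their sum. This encoding is the
convention of the splice-aware quantification ecosystem; the detection
rule is deliberately strict so ordinary gene identifiers ending in "-U"
in a non-splice-aware run cannot trigger a spurious collapse.

## The two-stage cell-calling model

### Stage 1: order-of-magnitude knee estimation

Let $b$ be the barcodes sorted by total UMI count in descending order
(stable sort; ties keep file order). For a candidate cell number $c$,
let $m(c)$ be the 99th-percentile UMI count among the top $c$ barcodes,
and define the observed cell count as the number of barcodes whose total
strictly exceeds $m(c)/10$ — one order of magnitude below the top
population's high quantile. The selected cell number minimizes the loss

$$L(c) = \frac{(c^{o} - c)^2}{c},$$

where $c^{o}$ is the observed count at candidate $c$. The top $c^\ast$
barcodes of the ranking are retained outright and bypass the second
stage.

Numerical choices:

* **Percentile.** Linear interpolation between order statistics (the
  common "type 7" definition). The reference quantile at a 1-element
  list is the element itself.
* **Candidate grid.** A geometric series $\mathrm{round}(10^x)$ with
  2000 points of $x$ spanning $[0, \log_{10} n_{\mathrm{nonzero}}]$,
  deduplicated and clipped. Above roughly $c = 200$ this grid's integer
  spacing exceeds 1, so the literal grid argmin can sit one or two
  integers away from the exact integer argmin. Because the loss is zero
  exactly at $c = c^{o}$ when the data have a clean knee, we add a local
  refinement: every integer between the grid neighbours of the coarse
  argmin is also evaluated, and the final argmin is taken over the
  union. The refinement evaluates the same loss — it only removes the
  grid's resolution limit — and typically adds a handful of candidates.
* **Ties.** The smallest candidate wins, which is the conservative
  (fewest retained cells) choice.

### Stage 2: ambient-profile multinomial rescue

Barcodes outside the knee set with at least `umi_floor = 500` total UMIs
are tested against the ambient RNA profile. The ambient profile is
estimated from the pooled counts of barcodes with totals in
$[1, \min(100, \mathrm{umi\_floor}/5)]$ (excluding knee-retained
barcodes), smoothed with a pseudocount of 0.5 per gene and normalized, so
it is strictly positive. The pseudocount replaces the Good–Turing
frequency smoothing of the original empty-droplet test: it is simpler,
monotone, and adequate at the scale this tool targets; this is a stated
deviation, and the pool bounds are recorded in the output metadata.

Each candidate with count vector $x$ and total $T$ is scored by the
multinomial log-likelihood under the ambient profile $p$,

$$\ell(x) = \log \Gamma(T+1) - \sum_g \log \Gamma(x_g + 1)
          + \sum_g x_g \log p_g,$$

computed in log-gamma form for stability. Candidates are grouped by
identical total $T$; for each distinct total, `n_simulations = 10000`
multinomial draws of size $T$ from $p$ are scored, and the Monte-Carlo
p-value is

$$p = \frac{1 + \#\{\ell_{\mathrm{sim}} \le \ell_{\mathrm{obs}}\}}
           {1 + n_{\mathrm{sims}}},$$

the standard positively-biased estimator that never returns 0 and is
bounded below by $1/(n_{\mathrm{sims}}+1)$. Ties in log-likelihood are
counted with an absolute tolerance of $10^{-9}$ so exact ties on
discrete inputs are not lost to floating-point noise. Draws are made per
distinct total in ascending order from a single seeded stream, so the
p-values are deterministic given the seed and invariant to candidate
order.

P-values are adjusted by the Benjamini–Hochberg step-up (the procedure
behind "FDR threshold" in both implementations this design follows);
candidates at or below the threshold join the retained set. The default
threshold is 0.01; 0.001 is applied only when requested explicitly or
when the chemistry tag is listed in `strict_chemistries` — which
chemistries warrant the stricter value is left as configuration because
no authoritative mapping is available. Note that the adjusted values
depend on the candidate set size, so raising `umi_floor` (shrinking the
set) is not mathematically guaranteed to shrink the rescued set, although
it does on all realistic fixtures we test.

## QC statistics

* **Sequencing saturation** $= 1 - \mathrm{UMIs}/\mathrm{mapped\ reads}$
  (0 when no reads), using the mapped-read count from the logs and the
  deduplicated UMI total from the matrix; reported absent rather than
  approximated when logs are missing.
* **Spliced ratio** $= (S+A)/(S+U+A)$ per cell, grouping ambiguous with
  spliced (ambiguous reads are, in expectation, most likely spliced);
  undefined (absent) at zero totals. Nuclei samples shift this
  distribution toward low values.
* **Mitochondrial fraction** per barcode, with genes identified by the
  conventional `MT-`/`mt-` symbol prefix or a user-supplied list. A 10%
  guideline is displayed in the report; it is never applied as a filter.
* **Summary medians** (UMIs, genes per cell) are over retained cells
  only, with the mean-of-central-pair convention for even sizes;
  mean reads per cell divides processed reads by retained cells.
* **Knee curves** are run-length compressed for plotting (plateau
  endpoints kept, zeros dropped for the log scale), which preserves the
  minimum, maximum and every retained endpoint value.

## Doublet scoring and embeddings

Artificial doublets are simulated by summing the counts of two distinct,
uniformly sampled observed cells (twice as many doublets as cells by
default). Observed and simulated cells are embedded jointly
(total-count normalization to the median observed depth, `log1p`, PCA to
30 components) and a k-nearest-neighbour graph ($k = 15$) is built in PC
space. A cell's raw score $q$ is the fraction of its neighbours that are
simulated; it is rescaled to $q / (r(1-q) + q)$ for the
simulated:observed ratio $r$, so an unenriched neighbourhood scores near
the doublet prior rather than near $r/(1+r)$. The threshold is the
minimum-density point between the two largest modes of the simulated
score distribution (kernel density, modes below 5% of the peak ignored).
When that distribution is effectively unimodal — e.g. homogeneous data
where doublets are indistinguishable — no cells are flagged and a
warning is emitted, since the rule presumes bimodality.

The visualization pipeline is the standard one: normalize, `log1p`,
top-2000 highly-variable genes by dispersion, PCA, then UMAP and t-SNE
with fixed seeds. The 2-D projections delegate to the reference
implementations (umap-learn, scikit-learn) through a bundled helper
invoked as a subprocess, since no R implementation is available in the
supported environment; normalization, HVG selection and PCA are native.
Inputs below 30 cells, or with a degenerate gene axis, skip the
embedding with a warning — report generation must never fail on thin
inputs.

## The synthetic generator: its world and its limits

`synthetic_truth()` / `simulate_experiment()` emulate the input regimes
the tool is designed to assess: a high-depth true-cell population
(log-normal totals, default meanlog $\log 2000$, sdlog 0.3 — a
realistic depth spread for droplet data), a large low-depth ambient
population (uniform-log totals in $[1, 100]$, giving the sharp knee of
healthy libraries and at least an order of magnitude of separation),
optional planted doublets (cross-population pair sums), per-UMI splice
statuses drawn from a fixed $(S, U, A)$ simplex point
($(0.60, 0.25, 0.15)$ for whole cells, $(0.15, 0.75, 0.10)$ as a
nuclei-like preset), mitochondrial gene labels, and step logs whose
read totals are derived from planted mapping-rate and saturation values.
Population expression programs are Dirichlet-like gamma draws with a
population-private up-weighted gene block, and the ambient profile is a
flatter, distinct background.

What it does **not** emulate: real transcriptome structure (gene-gene
correlation, dropout beyond multinomial sampling), barcode-error
artifacts, depth-dependent splice fractions, or the "damaged cell"
mid-range continuum of compromised libraries. A green test on these
fixtures establishes algorithmic correctness against planted truth —
not performance on pathological real-world libraries.

## Degenerate inputs and error policy

All-zero matrices refuse to rank; an empty candidate grid after clipping
is an error; an empty ambient pool downgrades the rescue stage to a
warning (the knee set is still returned); zero retained cells produce a
summary with absent medians and a prominent warning; malformed log files
warn and leave fields absent (never zero); log inconsistencies (mapped >
processed) are surfaced as warnings, not silently repaired. The HTML
report renders with any subset of optional sections absent, each marked
skipped with its reason.

## Known limitations

* The ambient pool bounds and pseudocount smoothing are pragmatic
  defaults, not the original Dirichlet-multinomial estimation of the
  empty-droplet literature; heavily contaminated libraries may warrant
  the full model.
* Monte-Carlo p-values are exact-in-the-limit but discrete at
  $1/(n_{\mathrm{sims}}+1)$; with very many candidates at the same
  total, BH granularity interacts with that floor.
* The HDF5 container work is delegated to the canonical `anndata`
  implementation through a bundled Python helper; an environment without
  `python`/`anndata` on the PATH can use the quantification-directory
  path but not `.h5ad` input/output.
* Doublet thresholding presumes bimodal simulated scores; homogeneous
  datasets are deliberately left unflagged.
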