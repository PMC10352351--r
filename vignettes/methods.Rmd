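---
title: "Methods: pseudo-bulk RUV-III integration of multi-sample single-cell data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudo-bulk RUV-III integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and its assumptions

`fastruv` removes unwanted (batch, cohort, study) variation from a
cells × genes expression matrix using the RUV-III factor model

$$Z_{C\times G} = X_{C\times p}\,\beta_{p\times G} + W_{C\times k}\,\alpha_{k\times G} + \epsilon_{C\times G},$$

where $Z$ is log-transformed, cosine-normalized and gene-wise standardized
expression, $X\beta$ is the biological (wanted) component, and $W\alpha$ the
unwanted component. Neither $X$ nor $\beta$ is ever estimated: the wanted
structure enters only implicitly, through the *replicate matrix* $M$ (which
observations are assumed biologically equivalent) and the *negative-control
genes* (which genes are assumed to carry no biological signal of interest).
The method's assumptions are exactly those two: replicate sets are
biologically homogeneous, and stably expressed genes (SEGs) vary only
through unwanted factors. Everything else is linear algebra:

* $\hat\alpha$ = first $k$ right singular vectors of $R_M Z_b$, with
  $R_M = I - M(M^\top M)^{-1}M^\top$ the projector that centers each
  replicate set, computed on the pseudo-bulk sketch $Z_b$;
* $\hat W = Z_s\hat\alpha_s^\top(\hat\alpha_s\hat\alpha_s^\top)^{-1}$ on the
  full matrix restricted to the SEG columns $s$;
* $\hat Z = Z - \hat W\hat\alpha$, then inverse standardization.

The pseudo-bulk sketch makes the SVD cost independent of the cell count.
With subset size 1 the sketch *is* the matrix, and the test suite verifies
that the pipeline then reproduces a dense implementation of the three steps
to 1e-8.

## Pipeline stages and tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `hvg_n` | 2000 | HVGs used for clustering and MNC centroids. Per batch, a loess trend (span 0.3) of per-gene variance vs mean is fitted, genes are ranked by residual variance, and ranks are averaged across batches; ties break by gene ID so results are platform-stable. `NULL` (all features) for low-feature modalities such as ADT or CyTOF panels. |
| `n_neighbors` | 10 | kNN size of the within-batch SNN graph. Edge weight is the Jaccard overlap of kNN sets (the dominant SNN convention; the weighting is not pinned down by the method description); zero-weight edges are dropped. |
| `resolution` | 1.0 | Louvain resolution. The number of clusters is never prespecified. |
| `k_pseudobulk` | 30 | pseudo-bulk per (batch, condition, group) cell. Groups smaller than this pass through as single-cell rows, so rare populations are never averaged away. |
| `strategy` | `mean_random_split` | gene-wise means of a seeded random split. Pool-and-divide variants (gene-wise sums; library-size-ordered or random assignment) are provided for count data; the optional negative-binomial redraw of pooled sums is off by default because it does not improve integration quality, and its dispersion must then be supplied by the user. |
| `per_condition` | TRUE | build the MNC graph within each condition, so condition effects can never enter the replicate residual. Conditions present in a single batch contribute singleton sets only. |
| `mnc_metric` | `pearson` | centroid distance 1 − r, robust to residual per-batch scaling; Euclidean available. |
| `k_ruv` | 20 | number of unwanted factors. Field practice: 20 for scRNA-seq, 10 for ADT/CyTOF, smaller values (3) for small antibody panels. Clamped to the residual rank with a warning rather than erroring, so sensitivity sweeps run on small data. `k_ruv = 0` is an exact no-op. |
| `seg_quantile` | 0.2 | fraction of genes kept by the fallback stability score when no SEG list is given. |

Grouping can also adopt user-supplied cell-type labels (reference-based
workflow); the downstream pipeline is identical in either case.

### Replicate sets from the MNC graph

Connected components of the mutual-nearest-cluster graph define the
replicate sets. This is a deliberate simplification of the multi-step
refinement used by earlier RUV-based integration tools: components are the
plainest reading of "clustering on the MNC graph", they are deterministic,
and singleton nodes (batch-unique populations) become singleton sets whose
residual is exactly zero — unique cell types are untouched during factor
estimation. Nearest-cluster search uses node centroids rather than all
pairwise pseudo-bulk distances, for determinism and cost; ties break by node
ID order.

### Hierarchical merging

A merge tree holds ordered levels of disjoint collections; each collection
names the metadata column that serves as the batch label at that level
(cohort below, study above) and may override `k_ruv`, `k_pseudobulk` and
`per_condition`. Standardization statistics, HVGs and grouping are
recomputed per collection per level: each level's output is a new log-scale
matrix, and recomputation keeps the model assumptions valid at every level
(the alternative — freezing level-1 statistics — is cheaper but mixes
scales). A flag-free special case: the flat run is exactly a one-level,
one-collection tree, and the suite asserts bit-identity. Counts are
log-normalized and cosine-normalized once, globally, before the first
level, so pass-through cells stay on a coherent scale.

## Normalization and numerical choices

* **Log base 2, pseudocount 1**, size factors = library size / mean library
  size. The convention of the standard normalization tools; configurable.
* **Cosine normalization is not inverted** on output: the adjusted matrix is
  returned on the (cosine-scaled) log scale by inverting the gene-wise
  standardization only. Tools in this lineage return log-scale matrices; the
  per-cell norm is a technical quantity with no biological meaning after
  adjustment.
* **Zero-variance genes** are flagged, carried through unadjusted, and
  restored verbatim.
* **Standardization** uses the $n-1$ variance denominator.
* **Sign convention**: each row of $\hat\alpha$ has its largest-magnitude
  entry positive, making output bit-stable across linear-algebra backends.
* **Rank deficiency**: $k$ is clamped to the rank of $R_M Z_b$ (singular
  values above `max(dim) * max(d) * eps`); a residual matrix that is
  identically zero is an error ("no within-replicate variation").
* **Ill-conditioning** of $\hat\alpha_s\hat\alpha_s^\top$ (condition number
  > 1e10) switches to the Moore–Penrose pseudo-inverse with a warning.
* **Seeding**: one user seed drives every stochastic stage through
  independent substreams keyed by level, collection index and stage name, so
  adding a stage never perturbs earlier draws and identical inputs give
  bit-identical outputs.

## The synthetic-data generator

`simulate_counts()` draws negative-binomial counts with mean
$\mu_{gt}\cdot e^{\eta_s}\cdot FC_{batch}(g,b)\cdot FC_{ds}(g,t,c)$ and
per-gene dispersion $\theta_g$:

* base means $\mu_{gt}$ log-normal(meanlog 0.5, sdlog 1.2) per gene and cell
  type; dispersions gamma(shape 2, rate 1). These stand in for marginals
  that would otherwise be fitted to a real training dataset, which is out of
  scope here.
* per-sample shifts $\eta_s \sim N(0, 0.1)$ emulate sample-level random
  effects;
* batch fold changes are log-normal(meanlog $\log 2$, sdlog 0.43) draws with
  a random sign of the log-effect per gene *and* batch (batch 1 as
  reference). The per-gene-per-batch sign (rather than one global sign per
  gene) is the more general reading of "direction randomly assigned";
* DS genes: a fraction (5 or 10%) of genes per cell type receive a log2
  fold change drawn log-normal(meanlog $\log \mu_{lfc}$, sdlog 0.43),
  applied to condition 2 with a Bernoulli(1/2) direction. With
  $\mu_{lfc} \in [1.1, 2]$ the typical log2 FC is 1.1–2, matching the
  stated grid; the batch draw, by contrast, is itself the multiplicative
  fold change (median 2).
* sample-to-batch assignment is deterministic: `confound = 0.5` is balanced;
  0.8 places 80% of each condition's samples in "its" batch, planting the
  partial batch–condition alignment used in the DS benchmarks.

What it does **not** emulate: gene–gene correlation (no copula; genes are
conditionally independent given the design), ambient RNA, doublets, or
empirical library-size distributions. Passing tests therefore demonstrate
correct removal of multiplicative per-gene batch effects under NB noise —
not performance under every artefact of real data.

`simulate_ruv_model()` draws every term of the factor model exactly
(orthonormal $\alpha$, $X$ = one-hot replicate design, $\beta$ zeroed on a
held-out SEG gene set) and is the oracle for the estimator tests: with
$\epsilon = 0$, the true $k$ and the zero-$\beta$ genes as controls, the
pipeline recovers $X\beta$ to relative Frobenius error below 1e-6.

## Evaluation metrics

* **ARI** (pair-counting, chance-corrected) of a Louvain clustering of the
  top-20-PC embedding against cell-type labels (signal) and batch labels
  (noise); cross-checked in the suite against an independent implementation.
* **ASW**: mean silhouette width, Euclidean distance, computed on the
  top-20-PC embedding by default. The UMAP variant used in visual
  benchmarking is intentionally not the default: UMAP is stochastic and its
  hyper-parameters are unstated, while the PC embedding preserves the
  metric's ordering behaviour deterministically.
* **PCA score**: $\sum_i \text{varfrac}_i \cdot R^2_i$ over the first 20
  PCs, $R^2_i$ from regressing PC scores on the technical label; lower is
  better.
* **DS testing**: cells aggregated to gene × sample means per cell type,
  then a moderated two-group t-test with a mean–variance trend (the
  limma-trend algorithm, via limma). BH correction is applied within each
  cell type, matching the per-cell-type framing; global correction is a
  flag. FDR/TPR/F1 against simulation truth use the conventions FDR = 0 and
  F1 = 0 when nothing is called.

## Problem sizes used by the test suite

The shipped benchmarks are deliberately compact versions of the study
designs they mirror: the default scenario is 2 batches × 2 conditions ×
3 cell types, 8 samples × 100 cells, 500 genes; the DS benchmark keeps the
23-sample two-condition design at 100 cells per sample and 500 genes; the
sensitivity grids (pseudo-bulk 10–50, neighbours 5–30, k 10–30, varied one
at a time) run at 8 samples × 50 cells and 300 genes. The published-scale
design (23 samples × 800 cells = 18,400 cells) is exercised through the
simulator entry point, which reproduces it exactly. These sizes are the
package's own choice of test economy; all thresholds are properties
(orderings and identities), not tuned constants.

## Known limitations

* Per-cell normalization (size factors, cosine) is compositional: strong DS
  genes perturb every other gene's normalized value slightly, which inflates
  the *absolute* FDR of sample-level DS testing on any per-cell-normalized
  matrix, adjusted or not. The suite therefore asserts the comparative
  claims (adjustment raises F1 and lowers FDR relative to raw confounded
  data), which are robust to this artefact.
* The fallback SEG stability score (expression-proportion rank + batch-mean
  residual-variance rank) is a documented heuristic, not the published SEG
  derivation; a curated SEG list is the recommended input and takes
  precedence when supplied.
* Replicate sets are graph components, not the multi-step MNC refinement of
  earlier tools; on data where two genuinely distinct populations are each
  other's mutual nearest clusters across batches they would be pooled.
* The merge order is user input; no data-driven inference of the tree is
  attempted.
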