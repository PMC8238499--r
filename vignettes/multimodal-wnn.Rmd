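---
title: "Weighted nearest neighbor integration: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted nearest neighbor integration: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiweave)
```

## The problem

Multimodal single-cell assays measure two or more molecular layers in the
same cells. Integrating them into one representation must respect a basic
asymmetry: the relative information content of each layer differs *between
cells*, not just between datasets. An antibody panel with anti-CD4 and
anti-CD8 distinguishes T-cell subsets that transcriptomes blend; the same
panel may carry nothing that distinguishes dendritic cells, which the
transcriptome separates easily. A single global mixing ratio is therefore
the wrong object; `multiweave` estimates a per-cell weight for each
modality and combines similarities cell by cell.

## Model

Each modality is normalized and embedded independently:

* RNA: library-size log-normalization,
  `ln(1 + scale_factor * x / colsum)`, then PCA (features centered and
  scaled by default) — `log_normalize()`, `pca_embed()`.
* Protein (ADT): centered log-ratio within each cell with a +1 pseudocount
  and natural log, then PCA — `clr_normalize()`. The within-cell margin is
  the default because ADT composition, not magnitude, is comparable across
  cells; the per-feature margin is exposed for very large panels.
* Chromatin: TF-IDF (term frequency = per-cell share of accessibility;
  inverse document frequency = `n_cells` / peak total, with a binary
  alternative), `ln(1 + 1e4 * TF * IDF)`, then LSI: truncated SVD with each
  component standardized to mean 0, sd 1, and component 1 dropped by
  default since it usually tracks sequencing depth — `tfidf_normalize()`,
  `lsi_embed()`.

Every embedding is row-L2-normalized once at construction; all downstream
distances are Euclidean on these unit vectors (equivalently, cosine
distances on the raw scores). This makes bandwidths comparable across
modalities with different dimensionalities.

For each modality a k-nearest-neighbor graph is built (`k = 20` by
default). For cell $i$ and modalities $m, n$:

* within-modality prediction: mean of the modality-$m$ embeddings of $i$'s
  modality-$m$ neighbors; cross-modality prediction: the same mean over the
  modality-$n$ neighbors;
* affinity: $\theta = \exp(-\max(d - d_1, 0) / (\sigma_i - d_1))$ with $d$
  the Euclidean prediction error, $d_1$ the distance to the first neighbor
  (local connectivity, subtracted as in UMAP's kernel), and $\sigma_i$ the
  cell-specific bandwidth below;
* ratios $s_{mn}(i) = \theta_{mm} / (\theta_{mn} + \varepsilon)$ with
  $\varepsilon = 10^{-4}$ fixed; a softmax over all ordered pairs gives
  weights $w_m(i) \ge 0$, $\sum_m w_m(i) = 1$. With two modalities this is
  exactly $w_1 = e^{s_1} / (e^{s_1} + e^{s_2})$; the implementation
  subtracts the per-cell maximum before exponentiating, which changes
  nothing mathematically but stays finite when a cross-affinity underflows
  and a ratio hits its $1/\varepsilon$ ceiling.

The WNN graph scores candidate neighbors with
$\theta_\mathrm{weighted}(i,j) = \sum_m w_m(i)\,\theta_m(i,j)$, where
$\theta_m(i,j)$ reuses the same kernel with cell $i$'s bandwidth and local
connectivity. Candidates are the union of per-modality 200-NN lists
(clamped to $n - 1$ on small data); the top $k$ per cell are kept. The
similarity is deliberately asymmetric — it is always computed from the
query cell's weights and kernel. The graph's Jaccard SNN matrix feeds
community detection and UMAP.

### Bandwidth selection

A fixed-quantile bandwidth (distance to the k-th neighbor) penalizes rare
populations. Instead, for each cell we find the 20 cells with the *lowest
nonzero* Jaccard neighborhood overlap — cells near the margin of the
cell's state: similar enough to share neighbors, unlikely to share a
state — breaking Jaccard ties toward the furthest cells, and average their
Euclidean distances. Cells with fewer than 20 such partners use all of
them; cells with none (isolated duplicates, degenerate embeddings) fall
back to the k-th-neighbor distance and are flagged. Bandwidths are floored
at $d_1 + 10^{-10}$ so the kernel denominator stays positive. The Jaccard
sets include the cell itself (the common SNN convention; configurable),
and the low-Jaccard search only ever touches neighbors-of-neighbors, since
$J(i,j) > 0$ requires a shared neighbor.

## Supervised PCA and reference mapping

PCA directions maximize variance, which may be cell cycle or noise.
Supervised PCA instead maximizes the Hilbert-Schmidt Independence Criterion
between the projected transcriptome's linear kernel and a response kernel
$L$: the solution is the top-$d$ eigenvectors of $X H L H X^\top$ with $H$
the cell-centering matrix. Setting $L$ to the WNN SNN matrix makes the
loadings the transcriptomic directions that best reproduce the joint
multimodal structure — computable for any query that measured only RNA.
`spca_fit()` keeps $L$ sparse and never materializes an $n \times n$ dense
product; with $L = I$ it reduces exactly to PCA of the cell-centered
matrix, which the tests assert against a dense eigensolver.

Mapping proceeds: `spca_project()` centers the query with the reference
feature means (missing features contribute zero; a warning fires below 50%
overlap) and L2-normalizes the projected rows; `find_anchors()` keeps
mutual nearest neighbor reference-query pairs, scored by the Jaccard
overlap of their neighborhoods in the combined embedding; and
`transfer_labels()` lets each query cell's `k_weight` nearest anchors vote
for their reference label, weighted by a Gaussian kernel whose bandwidth is
the distance to the `k_weight`-th anchor, times the anchor score (plus a
tiny floor so equal-score ties still split evenly). Ties in the argmax go
to the first label in level order. Query visualization offers both the
reference-layout transform (novel populations get pushed to cluster
boundaries) and a de-novo merged UMAP (novel populations stay distinct);
computing both is recommended.

## The synthetic generator

`simulate_multimodal()` draws cluster-structured data with an explicit
asymmetry map: a cluster pair marked "separable only in modality $m$"
shares its centroid *exactly* in every other modality. Centroids and
per-feature baselines derive deterministically from the design seed, so
reference and query draws share generative parameters; cell draws use a
separate seed. Counts mode produces negative-binomial counts through a log
link (exercising the normalization path); gaussian mode emits log-scale
matrices directly for fast kernel tests.

The standard fixture (`asymmetric6_design()`) has six equal clusters,
n = 2000: an RNA-like modality (1000 genes, 10% markers per cluster with
log-scale effect sd 2.5, baseline log-mean $\ln 8$, NB dispersion 0.1 —
roughly a high-quality droplet library restricted to its variable genes)
and a protein-like panel (25 ADTs, 40% markers at effect sd 2, baseline
$\ln 20$, dispersion 0.1 — a deeply sequenced antibody panel). Pair A/B
shares its RNA centroid (CD4/CD8-like), pair C/D its protein centroid
(cDC-like). These depths were calibrated once, against two design
contracts: the separable pair must show a mean silhouette above 0.5 in its
separable modality and near 0 in the degenerate one, and a modality
corrupted by sd-5 Gaussian noise must end up with near-zero weight.
Shallower settings fail both — not because the weighting misbehaves, but
because a thin, noisy panel genuinely carries little information, and the
weights honestly say so.

What the generator does *not* emulate: ambient contamination, doublets,
batch effects, depth gradients correlated with state, or partially
(rather than exactly) shared centroids. Real CD4/CD8 T cells are partially
blended in RNA, not identical; an RNA-projected query can therefore
recover them in real data, but no estimator can split a pair whose RNA
distributions are *exactly* equal. The end-to-end mapping test accordingly
uses a mirrored design whose special pairs are separable in RNA and
degenerate in protein — the reference WNN graph still has to rescue those
pairs from the uninformative panel, and the sPCA projection has to carry
the separation into the query space, so the full chain is exercised.

## Numerical and design choices

* Exact KNN (dense distances, ties broken by cell index) up to 5000 cells;
  a deterministic kd-tree backend beyond. All stochastic steps take seeds.
* $\varepsilon = 10^{-4}$, candidate width 200, `k = 20`, 20 bandwidth
  cells: fixed defaults of the method.
* Degenerate inputs: zero-library cells are an error (QC is the caller's
  job); all-zero peaks are dropped with a warning; constant LSI components
  error; zero-norm embedding rows stay zero and are flagged.
* The variable-gene homogeneity metrics fit the dropout-vs-mean (threshold
  0.1) or sd-vs-mean (threshold 0.5) trend with a Gaussian kernel smoother.
  The default bandwidth is *half* the Silverman rule (converted to
  `ksmooth` units): Silverman targets density estimation and visibly
  over-smooths the steep dropout trend, producing spurious "variable" calls
  in homogeneous data. Configurable.
* Marker panels: greedy forward selection under balanced (class-weighted)
  ridge logistic regression, 5-fold CV, ridge penalty chosen from
  {0.1, 0.01, 0.001} inside the same CV; abundant clusters are downsampled
  to a 5% cap first; the first five picks must be positive markers
  (higher target mean and positive coefficient). Enrichment is reported as
  precision / prevalence of the 0.5-boundary gate.
* Cross-cluster edge counts use the directed KNN convention (each row emits
  k edges); an undirected option collapses reciprocal pairs.
* Perturbation scores: per-gene Wilcoxon (BH-adjusted p < 0.1) defines the
  gene set; an empty set is a defined "no response detected" result, not an
  error.

## Problem sizes

The test suite runs the full workflow at n = 2000 cells (the fixture's
design size) for the graph-level properties, 20 seeds for the
cross-cluster separation check, and n ≤ 200 for the brute-force oracle
comparisons, where every quantity — neighbor lists, Jaccard matrices,
bandwidths, affinities, weights, WNN top-k, MNN anchors — is checked
against naive dense re-implementations.

## Limitations

* Weights are per cell, not per feature; a modality that is informative
  for only a few of its features is weighted as a whole.
* The exact-sharing asymmetry map is a stress test, not a realistic model
  of partially blended populations.
* sPCA mapping transfers only what the transcriptome can express: states
  defined purely by another modality with *no* transcriptomic correlate
  cannot be recovered in an RNA-only query.
* Community detection, UMAP, and truncated SVD are delegated (igraph,
  uwot, irlba); their internals are out of scope and asserted only
  behaviorally.
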