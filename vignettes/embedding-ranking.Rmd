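---
title: "Ranking spatial-transcriptomics embeddings by message passing and Moran's I"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking spatial-transcriptomics embeddings by message passing and Moran's I}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpmim)
```

## Why rank embeddings at all

Spatial transcriptomics models produce a low-dimensional embedding per
spot, and downstream tissue-architecture identification (clustering, image
segmentation) is only as good as that embedding. Hyperparameter sweeps
produce many candidates whose quality varies sample by sample, and the
natural quality measure — adjusted Rand index (ARI) of a clustering
against expert annotation — needs exactly the labels one usually lacks.
The method implemented here scores embeddings *label-free*: an embedding
whose dimensions vary coherently across the tissue carries more usable
spatial structure than one dominated by spot-level noise, and global
spatial autocorrelation quantifies that coherence.

## The procedure and its assumptions

Given an embedding matrix $H \in \mathbb{R}^{n \times D}$ over $n$ spots
with 2-D coordinates:

**1. Embedding-space KNN graph.** Every spot links to its `k_num` nearest
spots by Euclidean distance *in embedding space* (not physical space —
the graph should connect spots the model considers similar, wherever they
sit on the slide). The edge set is symmetrized by union, which preserves
connectivity for message passing. Neighbour lists are then pruned
adaptively: within each node's list, neighbours farther than
mean + 1 sd (population sd) of that node's neighbour distances are
removed, the single nearest neighbour always survives, and symmetry is
restored by union. The cited pruning idea gives no formula, so the
mean-plus-one-sd rule is this package's concrete choice: it is scale-free,
removes only minority outliers, and never isolates a node. It is applied
exactly once (re-applying could shave further neighbours; a single pass
matches the stacked-layer semantics where the graph is fixed).

**2. Message passing.** With aggregation weights $\alpha_{ij}$ over the
pruned neighbourhood $N_i$, each layer replaces
$h_i \leftarrow \sum_{j \in N_i} \alpha_{ij} h_j$, dimension by dimension,
and `l_num` layers are stacked with the graph *and* the weights frozen
(both computed once from the input embedding). Two weightings exist:

* *distance softmax* — $\alpha_{ij} = e^{d_{ij}} / \sum_{k} e^{d_{ik}}$
  with raw embedding distances in the exponent, so **farther neighbours
  get larger weight**. This is intentional: ordinary graph convolutions
  already privilege short-range structure, and the transform is meant to
  fold long-range dependency into the embedding before scoring.
* *basic* — $\alpha_{ij} = 1/|N_i|$, a plain neighbourhood mean.

There are no nonlinearities, biases or trained parameters; each layer is a
row-stochastic linear map, so transformed values stay inside the
per-dimension input range and `l_num = 0` is the identity.

**3. Autocorrelation scoring.** Per dimension $x$, with binary spatial
weights $w_{ij}$ and $S_0 = \sum_{ij} w_{ij}$:

$$I = \frac{n \sum_{ij} w_{ij}(x_i - \bar x)(x_j - \bar x)}
          {S_0 \sum_i (x_i - \bar x)^2}, \qquad
  C = \frac{(n-1) \sum_{ij} w_{ij}(x_i - x_j)^2}
          {2 S_0 \sum_i (x_i - \bar x)^2}.$$

Weights are binary, not row-standardized — the formulas above normalise by
$S_0$ directly. Geary's C is reported as $1 - C$ so both statistics share
the sign convention (1 positive, 0 none, −1 negative). The embedding score
is the **maximum** of the per-dimension statistics: one strongly coherent
dimension is enough for downstream use, and empirically max filtering
separates embedding qualities more sharply than the average (minimum
filtering mostly reflects the worst dimension and is kept only for
comparison). Embeddings are ranked by descending score, ties broken by
ascending name for determinism.

The key assumption is that spatial coherence of the embedding is a proxy
for downstream clustering quality. That holds when tissue domains are
spatially contiguous (cortical layers, tumour regions); it would mis-rank
embeddings of tissues whose true domains are spatially interleaved.

## Parameters

| parameter | default | units | notes |
|---|---|---|---|
| `k_num` | 90 (distance), 9 (basic) | neighbours | larger values aggregate more per layer; must be `< n` |
| `l_num` | 15 | layers | ranking quality plateaus as layers increase; 0 disables the transform |
| `mp_type` | `"distance"` | — | softmax vs uniform weights |
| `weight_type` | derived | — | radius scheme with distance type, spatial-KNN with basic type; both selectable |
| `radius` | `"auto"` | coordinate units | auto = max nearest-neighbour distance, the smallest radius leaving no spot isolated |
| `knn_w` | 6 | neighbours | first hexagonal ring of a Visium array |
| `filter_type` | `"max"` | — | max / avg / min across dimensions |
| `statistic` | `"moran"` | — | Moran's I or 1 − Geary's C |
| `seed` | 1 | — | K-means restarts (10) in ground-truth ranking |

## Numerical choices and degenerate inputs

* **Softmax overflow.** The softmax exponentiates raw distances without
  the usual max-subtraction shift, preserving the literal weighting; any
  node whose largest neighbour distance exceeds 700 (the double-precision
  `exp` bound) falls back to uniform weights for that node only.
* **Self-exclusion.** $N_i$ excludes the node itself by default (a pure
  neighbour average); graph-convolution conventions differ, so
  `include_self = TRUE` is available.
* **Ties.** Nearest-neighbour distance ties break to the lower spot
  index; score ties in rankings break to the ascending embedding name.
* **Zero-variance dimensions.** Moran's I and Geary's C are undefined for
  constant fields; such dimensions return `NA` with a warning and are
  excluded from the max/avg/min reduction (scoring them 0 would distort
  the avg and min filters). An all-constant embedding is an error.
* **Duplicate coordinates.** Radius weights use $0 < d_{ij} \le r$, so
  coincident spots are never each other's neighbours under the radius
  scheme.
* **Spearman ties.** The classical $1 - 6\sum d_i^2 / (n(n^2-1))$ formula
  assumes distinct ranks; tie-averaged ranks (Pearson correlation of
  ranks) are used instead, with a two-sided p-value from the
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation.

## What the synthetic generator does and does not emulate

`make_lattice()` builds integer-grid or hexagonally offset (Visium-like)
lattices with unit spacing; `make_embedding()` builds each dimension as a
Gaussian-kernel-smoothed field over per-domain Gaussian levels
(standardised to unit variance) plus i.i.d. noise; `make_labels()` cuts
the lattice into contiguous bands that play the role of annotated layers.

`make_suite()` draws the smooth field **once** and gives the $m$ members
noise sd stepped geometrically from 4 down to 0.05. Sharing the field is
deliberate: the suite emulates one tissue represented at varying fidelity,
which is what makes "lower noise = better embedding" a true ordering. With
independent fields per member, low-noise members reorder by field-to-field
luck and no construction truth exists. The default benchmark is a 20×20
hex lattice (400 spots), 8 embeddings, 3 dimensions, 4 domains — sizes
chosen so the full benchmark (transform, score, K-means ground truth,
baselines, 10 seeds) runs in well under a minute.

What the fixtures do *not* emulate: count noise and library-size effects
(fixtures live directly in embedding space, matching the tool's input
contract), irregular tissue boundaries and holes, spatially interleaved
domains, and embeddings whose dimensions are correlated. Passing the
benchmark therefore shows the pipeline orders smoothness correctly under
controlled conditions — not that it resolves every failure mode of real
embeddings (the known hard case: embedding collections dominated by many
near-degenerate members can confound an autocorrelation-based score).

## Design decisions that were genuinely open

* **Union vs intersection symmetrization** (graph and spatial KNN
  weights): union, to keep the graph connected and because the
  construction is described as undirected.
* **Binary vs row-standardized spatial weights**: binary, matching the
  $S_0$-normalised formulas; the ape cross-check in the tests uses a
  degree-regular layout precisely because its reference implementation
  row-normalises.
* **Scheme pairing**: radius weights with the distance transform, spatial
  KNN with the basic transform, as defaults only — the pairing is
  configurable because no principled coupling exists.
* **Ground-truth K-means**: 10 restarts under a fixed seed, cluster count
  from the labels. Restart count and seeding are conventions, stated so
  results are reproducible; any clustering method could stand in.

## Known limitations

* The score is relative: it ranks embeddings of one sample and carries no
  calibrated meaning across samples or platforms.
* $O(n^2)$ exact distance computations cap practical use at a few
  thousand spots per embedding — comfortable for Visium sections, not for
  subcellular-resolution platforms.
* With the distance softmax, a single extreme outlier spot concentrates
  weight on itself for its neighbours (until the overflow guard trips);
  pruning removes most such edges first, but heavy-tailed embeddings are
  the stress case.
* Moran's I of a transformed embedding rises with smoothing by
  construction; scores are comparable only across embeddings transformed
  with the *same* configuration, which is how the ranking functions use
  them.

## A compact benchmark run

```{r benchmark}
xy <- make_lattice(10, 10)
suite <- make_suite(xy, m = 5, seed = 1)
cfg <- mpmim_config(k_num = 20, l_num = 5)
ranking <- rank_embeddings(suite$embeddings, xy, cfg)
tidy(ranking)
spearman_rank(tidy(ranking)[, c("name", "rank")],
              suite$truth[, c("name", "rank")])
```

The construction-best, lowest-noise member should head the ranking; the
acceptance script (`scripts/acceptance.R`) runs the full-size version of
this check over 10 seeds together with the analytic and oracle checks.
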