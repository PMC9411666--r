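# mpmim

Message passing + Moran's I with maximum filtering: selecting the best
embedding of a spatial transcriptomics sample.

## The problem

Deep-learning tools for spatial transcriptomics (graph autoencoders,
graph convolutional networks, ...) reduce each capture spot to a
low-dimensional embedding that downstream clustering or segmentation turns
into a tissue-architecture map. Sweeping hyperparameters yields dozens of
candidate embeddings per sample, and their downstream quality varies a lot
— but picking the good one normally requires the expert annotation you are
trying to predict. `mpmim` ranks candidate embeddings *without labels*, so
analysts can carry a handful of promising embeddings (or just the best
one) into clustering and segmentation.

## The method

For each candidate embedding `H` (spots × dimensions) with spot
coordinates:

1. **Graph construction.** Build a KNN graph in *embedding* space
   (Euclidean distance, `k_num` neighbours, symmetrized by union), then
   prune each node's list adaptively: neighbours farther than
   mean + 1 sd of that node's neighbour distances are dropped (the nearest
   is always kept).
2. **Message passing.** Stack `l_num` aggregation layers with frozen
   weights: `h'_i = Σ_{j∈N_i} α_ij h_j`, where
   `α_ij = exp(d_ij) / Σ_k exp(d_ik)` softmaxes the embedding distances —
   deliberately *up-weighting remote neighbours* to capture long-range
   dependency — or `α_ij = 1/|N_i|` for the basic graph convolution.
   Defaults: `k_num = 90, l_num = 15` (distance type); `k_num = 9` for the
   basic type.
3. **Scoring.** Per embedding dimension `x`, compute global Moran's I

   `I = n Σ_ij w_ij (x_i − x̄)(x_j − x̄) / (S0 Σ_i (x_i − x̄)²)`

   under a binary spatial weight matrix `w` (all spot pairs within a
   radius, or spatial KNN), then reduce across dimensions by **maximum
   filtering**: `score = max(I_0, …, I_D)`. Geary's C (reported as 1 − C)
   and average/minimum filtering are available for comparison.
4. **Ranking.** Sort embeddings by score, descending. Against expert
   labels, the reference ordering is each embedding's K-means ARI, and
   agreement is measured by Spearman correlation and a top-k report.

## Worked example

The built-in generator makes a Visium-like hex lattice and a suite of
embeddings that share one smooth spatial field but carry increasing noise
(`e01` worst … `e05` best), so the true quality order is known:

```r
library(mpmim)

xy     <- make_lattice(12, 12)               # 144-spot hex lattice
suite  <- make_suite(xy, m = 5, seed = 2)    # noise gradient e01..e05
cfg    <- mpmim_config(k_num = 20, l_num = 5)

ranking <- rank_embeddings(suite$embeddings, xy, cfg)
ranking
#> <mpmim_ranking> 5 embeddings, 144 spots; moran/max filter, k_num = 20, l_num = 5
#> # A tibble: 5 × 3
#>   name   score  rank
#>   <chr>  <dbl> <int>
#> 1 e05   0.943      1
#> 2 e04   0.940      2
#> 3 e03   0.873      3
#> 4 e02   0.526      4
#> 5 e01   0.0140     5
```

The max-filtered Moran's I tracks the construction order: the low-noise
embeddings score near 1 (strong spatial coherence in their best
dimension), the pure-noise-dominated `e01` scores near 0. Against the
label-based ground truth:

```r
truth <- ground_truth_ranking(suite$embeddings, suite$labels, seed = 2)
spearman_rank(tidy(ranking)[, c("name", "rank")], truth[, c("name", "rank")])
#> # A tibble: 1 × 4
#>     rho p_value rho_clamped     n
#>   <dbl>   <dbl>       <dbl> <int>
#> 1   0.9  0.0374         0.9     5

top_k_report(ranking, truth, k = 3)
#> # A tibble: 3 × 5
#>   name  predicted_rank score   ari truth_rank
#>   <chr>          <int> <dbl> <dbl>      <int>
#> 1 e05                1 0.943 0.742          1
#> 2 e04                2 0.940 0.623          3
#> 3 e03                3 0.873 0.664          2
```

The label-free ranking agrees with the ARI ordering at rho = 0.9, and the
truth-best embedding `e05` is ranked first. `autoplot()` works on ranking
and score objects; `tidy()`/`glance()` return tibbles throughout.

A command-line wrapper with `simulate`, `transform`, `rank` and
`evaluate` subcommands lives at `inst/cli/mpmim.R`
(`system.file("cli", "mpmim.R", package = "mpmim")` after installation);
it reads/writes delimited text and understands the 10x Visium
`tissue_positions_list.csv` convention via `--coords-dialect visium_positions`.

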