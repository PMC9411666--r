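# Default benchmark: hex 20x20 lattice (400 spots), 8-embedding noise
# gradient, default configuration (distance softmax, k_num 90, l_num 15,
# max-filtered Moran's I under radius weights). Computed once and shared by
# the tests that look at ranking recovery and baseline comparisons.

run_benchmark_seed <- function(seed) {
  xy <- make_lattice(20, 20)
  suite <- make_suite(xy, m = 8, seed = seed)
  cfg <- mpmim_config(seed = seed)
  ranking <- rank_embeddings(suite$embeddings, xy, cfg)
  pred <- tidy(ranking)[, c("name", "rank")]
  sp_constr <- spearman_rank(pred, suite$truth[, c("name", "rank")])$rho
  constr_best <- suite$truth$name[suite$truth$rank == 1]
  top5 <- top_k_report(ranking, suite$truth, k = 5)
  bl <- baseline_per_dimension(suite$embeddings, xy, suite$labels,
                               "moran", cfg)
  sp_truth <- spearman_rank(pred, bl$truth[, c("name", "rank")])$rho
  tibble::tibble(
    seed = seed,
    spearman_vs_construction = sp_constr,
    best_in_top5 = constr_best %in% top5$name,
    spearman_vs_ari_truth = sp_truth,
    baseline_best_spearman = bl$best$rho
  )
}

benchmark_results <- local({
  cache <- NULL
  function(seeds = 1:10) {
    if (is.null(cache)) {
      cache <<- purrr::map_dfr(seeds, run_benchmark_seed)
    }
    cache
  }
})
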