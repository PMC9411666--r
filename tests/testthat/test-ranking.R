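test_that("ari matches identity, relabeling and the enumerated 4-spot case", {
  expect_equal(ari(c(1, 1, 2, 2, 3), c(1, 1, 2, 2, 3)), 1)
  expect_equal(ari(c(1, 1, 2, 2, 3), c("b", "b", "c", "c", "a")), 1)
  # a = (1,1,2,2), b = (1,2,1,2): value frozen from the pair-counting oracle
  expect_equal(oracle_ari(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(ari(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_error(ari(1:3, 1:4), "length")
})

test_that("ari agrees with the pair-counting oracle on random partitions", {
  for (seed in 51:56) {
    set.seed(seed)
    n <- sample(5:30, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    expect_equal(ari(a, b), oracle_ari(a, b), tolerance = 1e-12)
  }
})

test_that("ari agrees with an established reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(77)
  a <- sample(1:4, 40, replace = TRUE)
  b <- sample(1:3, 40, replace = TRUE)
  expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
})

test_that("spearman_rank reproduces the classical rank-difference formula", {
  expect_equal(spearman_rank(1:5, 1:5)$rho, 1)
  rev5 <- spearman_rank(1:5, 5:1)
  expect_equal(rev5$rho, -1)
  expect_equal(rev5$rho_clamped, 0)
  # (1,2,3,4,5) vs (1,3,2,5,4): sum d^2 = 4, rho = 1 - 24/120 = 0.8
  expect_equal(spearman_rank(1:5, c(1, 3, 2, 5, 4))$rho, 0.8)
})

test_that("spearman_rank handles ties by average ranks and matches cor.test", {
  x <- c(1, 2, 2, 4, 5, 6)
  y <- c(2, 1, 4, 4, 6, 5)
  got <- spearman_rank(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = FALSE))
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)

  # explicit tie-averaged rank computation
  manual <- stats::cor(rank(x), rank(y))
  expect_equal(got$rho, manual, tolerance = 1e-12)
})

test_that("spearman_rank matches rankings by name for data-frame input", {
  a <- tibble::tibble(name = c("x", "y", "z"), rank = c(1, 2, 3))
  b <- tibble::tibble(name = c("z", "x", "y"), rank = c(3, 1, 2))
  expect_equal(spearman_rank(a, b)$rho, 1)
  bad <- tibble::tibble(name = c("x", "y", "q"), rank = 1:3)
  expect_error(spearman_rank(a, bad), "same set")
})

test_that("ground-truth ranking is deterministic and separates signal from noise", {
  xy <- make_lattice(8, 8)
  labels <- make_labels(xy, 4)
  onehot <- dplyr::bind_cols(
    tibble::tibble(spot = labels$spot),
    as.data.frame(stats::model.matrix(~ label - 1, labels))
  )
  set.seed(12)
  noise <- dplyr::bind_cols(tibble::tibble(spot = labels$spot),
                            as.data.frame(matrix(rnorm(64 * 4), 64, 4)))
  embs <- list(label_encoding = onehot, pure_noise = noise)
  gt <- ground_truth_ranking(embs, labels, seed = 42)
  expect_equal(gt$name[1], "label_encoding")
  expect_equal(gt$ari[1], 1)  # one-hot rows are perfectly separable
  expect_equal(gt$name[2], "pure_noise")
  expect_lt(gt$ari[2], 0.3)

  expect_identical(gt, ground_truth_ranking(embs, labels, seed = 42))

  short <- tibble::tibble(spot = labels$spot[1:10], label = labels$label[1:10])
  expect_error(ground_truth_ranking(embs, short, seed = 1), "labels missing")
})

test_that("rank_embeddings orders by score with name tie-breaks, independent of input order", {
  xy <- make_lattice(10, 10)
  suite <- make_suite(xy, m = 4, seed = 21)
  cfg <- mpmim_config(k_num = 15, l_num = 3)
  r1 <- rank_embeddings(suite$embeddings, xy, cfg)
  r2 <- rank_embeddings(rev(suite$embeddings), xy, cfg)
  expect_equal(r1$ranking, r2$ranking)
  expect_equal(sort(r1$ranking$rank), 1:4)
  expect_true(all(diff(r1$ranking$score) <= 0))

  # duplicated embedding: identical scores, tie broken by ascending name
  dup <- list(zz_copy = suite$embeddings$e04, aa_copy = suite$embeddings$e04)
  rd <- rank_embeddings(dup, xy, cfg)
  expect_equal(rd$ranking$score[1], rd$ranking$score[2])
  expect_equal(rd$ranking$name, c("aa_copy", "zz_copy"))

  bad <- suite$embeddings
  bad$e01 <- bad$e01[-1, ]
  expect_error(rank_embeddings(bad, xy, cfg), "e01")
})

test_that("without message passing a gradient outranks pure noise", {
  xy <- make_lattice(8, 8, "square")
  set.seed(33)
  embs <- list(
    gradient = tibble::tibble(spot = xy$spot, d1 = xy$x + xy$y),
    noise = tibble::tibble(spot = xy$spot, d1 = rnorm(64))
  )
  cfg <- mpmim_config(k_num = 5, l_num = 0)
  r <- rank_embeddings(embs, xy, cfg)
  expect_equal(r$ranking$name[1], "gradient")
  expect_gt(r$ranking$score[1], 0)
})

test_that("per-dimension baselines report Spearman per dimension and the best one", {
  xy <- make_lattice(12, 12)
  suite <- make_suite(xy, m = 5, seed = 9)
  cfg <- mpmim_config(seed = 9)
  bl <- baseline_per_dimension(suite$embeddings, xy, suite$labels, "moran", cfg)
  expect_equal(nrow(bl$per_dimension), 3)
  expect_true(all(bl$per_dimension$rho >= -1 & bl$per_dimension$rho <= 1))
  expect_equal(bl$best$rho, max(bl$per_dimension$rho))
  expect_equal(glance(bl)$best_dimension, bl$best$dimension)

  # single-dimension embeddings: baseline equals the filtered score ranking
  one_dim <- purrr::map(suite$embeddings, ~ .x[, c("spot", "dim1")])
  bl1 <- baseline_per_dimension(one_dim, xy, suite$labels, "moran", cfg)
  sw <- spatial_weights(xy, cfg)
  scores <- purrr::map_dbl(one_dim, ~ score_embedding(.x, sw)$score)
  ord <- order(-scores, names(scores))
  pred <- tibble::tibble(name = names(scores)[ord], rank = seq_along(scores))
  expect_equal(bl1$per_dimension$rho[1],
               spearman_rank(pred, bl1$truth[, c("name", "rank")])$rho)

  # the Geary baseline uses 1 - C, so its rho is sign-comparable
  blg <- baseline_per_dimension(suite$embeddings, xy, suite$labels, "geary", cfg)
  expect_equal(nrow(blg$per_dimension), 3)
})

test_that("top-k report flags whether the ground-truth best is captured", {
  pred <- tibble::tibble(name = c("a", "b", "c", "d"), rank = 1:4)
  truth <- tibble::tibble(name = c("b", "a", "d", "c"),
                          ari = c(0.9, 0.7, 0.4, 0.1), rank = 1:4)
  rep2 <- top_k_report(pred, truth, k = 2)
  expect_equal(rep2$name, c("a", "b"))
  expect_equal(rep2$ari, c(0.7, 0.9))
  expect_true(attr(rep2, "contains_truth_best"))

  rep1 <- top_k_report(pred, truth, k = 1)
  expect_false(attr(rep1, "contains_truth_best"))

  # k = m contains everything, flag necessarily true
  repm <- top_k_report(pred, truth, k = 4)
  expect_equal(nrow(repm), 4)
  expect_true(attr(repm, "contains_truth_best"))
  expect_error(top_k_report(pred, truth, k = 5), "exceeds")

  # identical rankings put the k largest ARIs on top
  repid <- top_k_report(truth[, c("name", "rank")], truth, k = 2)
  expect_equal(repid$ari, c(0.9, 0.7))
})
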