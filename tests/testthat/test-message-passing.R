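line_embedding <- function(vals) {
  tibble::tibble(spot = sprintf("s%02d", seq_along(vals)), d1 = vals)
}

test_that("distance-softmax weights follow the analytic small cases", {
  # single neighbour: softmax of one element is 1
  g1 <- knn_graph(line_embedding(c(0, 1, 10)), 1)
  w1 <- distance_weights(g1)
  expect_equal(w1$alpha[[1]], 1)
  expect_equal(w1$alpha[[3]], 1)

  # two neighbours at equal distance: (0.5, 0.5)
  expect_equal(w1$alpha[[2]], exp(c(1, 9)) / sum(exp(c(1, 9))))
  g_eq <- knn_graph(line_embedding(c(-1, 0, 1)), 2)
  expect_equal(distance_weights(g_eq)$alpha[[2]], c(0.5, 0.5))

  # distances 0 and ln 2 give weights (1/3, 2/3): the farther neighbour wins
  emb <- tibble::tibble(spot = c("a", "b", "c"), d1 = c(0, 0, log(2)))
  w <- distance_weights(knn_graph(emb, 2))
  expect_equal(w$alpha[[1]], c(1 / 3, 2 / 3))
  expect_gt(w$alpha[[1]][2], w$alpha[[1]][1])
})

test_that("overflow guard falls back to uniform weights per node", {
  emb <- tibble::tibble(spot = c("a", "b", "c"), d1 = c(0, 1, 800))
  g <- knn_graph(emb, 2)
  w <- distance_weights(g, overflow_guard = 700)
  expect_equal(w$alpha[[1]], c(0.5, 0.5))  # max distance 800 > guard
  # below the guard the softmax is used as-is
  w2 <- distance_weights(g, overflow_guard = 1000)
  expect_false(isTRUE(all.equal(w2$alpha[[1]], c(0.5, 0.5))))
})

test_that("uniform weights are 1/degree and identical across dimensions", {
  set.seed(2)
  emb <- dplyr::bind_cols(tibble::tibble(spot = sprintf("s%d", 1:10)),
                          as.data.frame(matrix(rnorm(30), 10, 3)))
  g <- knn_graph(emb, 4)
  w <- uniform_weights(g)
  for (i in 1:10) {
    expect_equal(w$alpha[[i]], rep(1 / length(g$nbr[[i]]), length(g$nbr[[i]])))
  }
})

test_that("all aggregation weights are nonnegative and row-sum to 1", {
  for (seed in c(1, 9)) {
    set.seed(seed)
    emb <- dplyr::bind_cols(tibble::tibble(spot = sprintf("s%d", 1:30)),
                            as.data.frame(matrix(rnorm(90) * 10, 30, 3)))
    g <- prune_graph(knn_graph(emb, 6))
    for (w in list(distance_weights(g), uniform_weights(g),
                   distance_weights(g, include_self = TRUE))) {
      expect_true(all(unlist(w$alpha) >= 0))
      expect_equal(vapply(w$alpha, sum, numeric(1)), rep(1, 30),
                   tolerance = 1e-9)
    }
  }
})

test_that("pass_layer aggregates neighbour values as stated", {
  # node b has neighbours a (value 2) and c (value 4); uniform -> mean 3
  emb <- tibble::tibble(spot = c("a", "b", "c"), d1 = c(2, 3, 4))
  g <- knn_graph(emb, 2)
  out <- pass_layer(emb, uniform_weights(g))
  expect_equal(out$d1[2], 3)

  # weights (1/3, 2/3) on values (3, 6) -> 5
  emb2 <- tibble::tibble(spot = c("a", "b", "c"),
                         pos = c(0, 0, log(2)), val = c(0, 3, 6))
  g2 <- knn_graph(emb2[, c("spot", "pos")] |>
                    dplyr::rename(d1 = pos), 2)
  w2 <- distance_weights(g2)
  expect_equal(w2$alpha[[1]], c(1 / 3, 2 / 3))
  agg <- sum(w2$alpha[[1]] * emb2$val[w2$nbr[[1]]])
  expect_equal(agg, 5)

  # constant embedding is a fixed point of any convex aggregation
  embc <- tibble::tibble(spot = sprintf("s%d", 1:5),
                         d1 = rep(7, 5), d2 = rep(-2, 5))
  gc_ <- knn_graph(embc, 2)
  outc <- pass_layer(embc, uniform_weights(gc_))
  expect_equal(outc$d1, rep(7, 5))
  expect_equal(outc$d2, rep(-2, 5))
})

test_that("pass_layer is linear in the embedding", {
  set.seed(4)
  base <- tibble::tibble(spot = sprintf("s%d", 1:15))
  h1 <- dplyr::bind_cols(base, as.data.frame(matrix(rnorm(30), 15, 2)))
  h2 <- dplyr::bind_cols(base, as.data.frame(matrix(rnorm(30), 15, 2)))
  g <- knn_graph(h1, 4)
  w <- distance_weights(g)
  a <- 2.5
  b <- -1.25
  combo <- dplyr::bind_cols(base, as.data.frame(
    a * embedding_matrix(h1) + b * embedding_matrix(h2)))
  lhs <- embedding_matrix(pass_layer(combo, w))
  rhs <- a * embedding_matrix(pass_layer(h1, w)) +
    b * embedding_matrix(pass_layer(h2, w))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("transformed values stay inside the per-dimension input range", {
  set.seed(8)
  xy <- make_lattice(8, 8)
  emb <- make_embedding(xy, n_dims = 3, smoothness = 1.5, noise_sd = 1,
                        seed = 8)
  cfg <- mpmim_config(k_num = 10, l_num = 6)
  out <- mp_transform(emb, cfg)
  m_in <- embedding_matrix(emb)
  m_out <- embedding_matrix(out)
  for (d in 1:3) {
    expect_gte(min(m_out[, d]), min(m_in[, d]) - 1e-12)
    expect_lte(max(m_out[, d]), max(m_in[, d]) + 1e-12)
  }
})

test_that("l_num = 0 is the identity and l_num = 2 composes pass_layer twice", {
  set.seed(5)
  emb <- dplyr::bind_cols(tibble::tibble(spot = sprintf("s%d", 1:20)),
                          as.data.frame(matrix(rnorm(40), 20, 2)))
  expect_identical(mp_transform(emb, mpmim_config(k_num = 5, l_num = 0)), emb)

  cfg <- mpmim_config(k_num = 5, l_num = 2, mp_type = "distance")
  g <- prune_graph(knn_graph(emb, 5))
  w <- distance_weights(g)
  twice <- pass_layer(pass_layer(emb, w), w)
  expect_equal(embedding_matrix(mp_transform(emb, cfg)),
               embedding_matrix(twice), tolerance = 1e-12)
})

test_that("uniform-weight transform equals the dense (D^-1 A)^l oracle", {
  set.seed(6)
  n <- 40
  emb <- dplyr::bind_cols(tibble::tibble(spot = sprintf("s%03d", 1:n)),
                          as.data.frame(matrix(rnorm(n * 3), n, 3)))
  cfg <- mpmim_config(k_num = 6, l_num = 4, mp_type = "basic")
  g <- prune_graph(knn_graph(emb, cfg$k_num))
  A <- as.matrix(graph_adjacency(g))
  P <- diag(1 / rowSums(A)) %*% A
  X <- embedding_matrix(emb)
  for (l in seq_len(cfg$l_num)) X <- P %*% X
  got <- embedding_matrix(mp_transform(emb, cfg))
  dimnames(X) <- dimnames(got)
  expect_equal(got, X, tolerance = 1e-10)
})

test_that("row-wise spread contracts under repeated uniform aggregation", {
  # 10 spots on a line, k = 3: the union graph contains triangles, so the
  # row-stochastic iteration converges instead of oscillating
  emb <- line_embedding(c(5, -3, 2, 8, 0, 1, -7, 4, 6, -2))
  g <- knn_graph(emb, 3)
  w <- uniform_weights(g)
  spreads <- numeric(30)
  cur <- emb
  for (l in 1:30) {
    cur <- pass_layer(cur, w)
    spreads[l] <- diff(range(cur$d1))
  }
  expect_true(all(diff(spreads) <= 1e-12))
  expect_lt(spreads[30], 0.05 * diff(range(emb$d1)))
})
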