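# Stacked neighbourhood aggregation over the embedding-space KNN graph.
# Each layer replaces a spot's feature vector by a convex combination of its
# neighbours' vectors; weights are fixed across layers. No nonlinearity, no
# trainable parameters - this is a deterministic smoothing transform.

new_weights <- function(nbr, alpha, ids, type) {
  structure(list(n = length(nbr), nbr = nbr, alpha = alpha, ids = ids,
                 type = type),
            class = "mpmim_weights")
}

maybe_add_self <- function(g, include_self) {
  if (!include_self) return(g)
  nbr <- lapply(seq_len(g$n), function(i) c(i, g$nbr[[i]]))
  dst <- lapply(seq_len(g$n), function(i) c(0, g$dist[[i]]))
  new_graph(nbr, dst, g$ids, g$k_num, g$pruned)
}

#' Distance-softmax aggregation weights
#'
#' Per node i, neighbour j gets weight
#' `alpha_ij = exp(d_ij) / sum_k exp(d_ik)` where `d_ij` is the
#' embedding-space Euclidean distance. Larger distances receive *larger*
#' weight by design: the aggregation emphasises long-range dependency that
#' short-range graph convolutions underweight. The softmax is applied to raw
#' distances with no stabilising shift; any node whose largest neighbour
#' distance exceeds `overflow_guard` falls back to uniform weights so
#' `exp()` stays finite.
#'
#' @param g An `mpmim_graph` (with stored distances).
#' @param include_self Include the node itself (at distance 0) in its own
#'   neighbourhood.
#' @param overflow_guard Distance above which a node's weights fall back to
#'   uniform. Default 700.
#' @return An `mpmim_weights` object; every weight vector is nonnegative
#'   and sums to 1.
#' @export
distance_weights <- function(g, include_self = FALSE, overflow_guard = 700) {
  stopifnot(inherits(g, "mpmim_graph"))
  g <- maybe_add_self(g, include_self)
  alpha <- lapply(seq_len(g$n), function(i) {
    d <- g$dist[[i]]
    if (max(d) > overflow_guard) {
      rep(1 / length(d), length(d))
    } else {
      e <- exp(d)
      e / sum(e)
    }
  })
  new_weights(g$nbr, alpha, g$ids, "distance")
}

#' Uniform aggregation weights (basic graph convolution)
#'
#' Every neighbour of node i receives weight `1 / |N_i|`.
#'
#' @inheritParams distance_weights
#' @return An `mpmim_weights` object.
#' @export
uniform_weights <- function(g, include_self = FALSE) {
  stopifnot(inherits(g, "mpmim_graph"))
  g <- maybe_add_self(g, include_self)
  alpha <- lapply(g$nbr, function(js) rep(1 / length(js), length(js)))
  new_weights(g$nbr, alpha, g$ids, "uniform")
}

weights_matrix <- function(w) {
  ii <- rep.int(seq_len(w$n), lengths(w$nbr))
  jj <- unlist(w$nbr, use.names = FALSE)
  xx <- unlist(w$alpha, use.names = FALSE)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(w$n, w$n))
}

#' Apply one message-passing layer
#'
#' Replaces every spot's feature vector by the weighted sum of its
#' neighbours' vectors, dimension by dimension:
#' `h'_i = sum_{j in N_i} alpha_ij h_j`. The node's own value enters only
#' if the weights were built with `include_self = TRUE`.
#'
#' @param embedding Embedding tibble, spot order matching the graph the
#'   weights came from.
#' @param w An `mpmim_weights` object.
#' @return Transformed embedding tibble, same shape and spot order.
#' @export
pass_layer <- function(embedding, w) {
  stopifnot(inherits(w, "mpmim_weights"))
  mat <- embedding_matrix(embedding)
  if (nrow(mat) != w$n) {
    abort(sprintf("embedding has %d spots but weights were built for %d.",
                  nrow(mat), w$n))
  }
  out <- as.matrix(weights_matrix(w) %*% mat)
  rownames(out) <- rownames(mat)
  as_embedding_tibble(out, dims = colnames(mat))
}

#' Transform an embedding by stacked message passing
#'
#' Builds the (optionally pruned) KNN graph once from the *input* embedding,
#' computes aggregation weights once, and applies `l_num` layers of
#' neighbourhood aggregation with graph and weights frozen. `l_num = 0`
#' returns the input unchanged. With increasing `l_num` the transform mixes
#' information from increasingly remote graph neighbourhoods.
#'
#' @param embedding Embedding tibble.
#' @param config An [mpmim_config()] (uses `k_num`, `l_num`, `mp_type`,
#'   `prune`, `include_self`, `overflow_guard`).
#' @return Transformed embedding tibble, same spots and dimensions.
#' @examples
#' emb <- make_embedding(make_lattice(6, 6), n_dims = 2, smoothness = 1,
#'                       noise_sd = 0.5, seed = 1)
#' mp_transform(emb, mpmim_config(k_num = 5, l_num = 3))
#' @export
mp_transform <- function(embedding, config = mpmim_config()) {
  stopifnot(inherits(config, "mpmim_config"))
  if (config$l_num == 0L) return(embedding)
  g <- knn_graph(embedding, config$k_num)
  if (config$prune) g <- prune_graph(g)
  w <- switch(config$mp_type,
    distance = distance_weights(g, config$include_self, config$overflow_guard),
    basic = uniform_weights(g, config$include_self)
  )
  W <- weights_matrix(w)
  mat <- embedding_matrix(embedding)
  for (l in seq_len(config$l_num)) mat <- W %*% mat
  out <- as.matrix(mat)
  rownames(out) <- embedding$spot
  as_embedding_tibble(out, dims = setdiff(names(embedding), "spot"))
}
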