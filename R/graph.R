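# KNN graph over embedding space: the communication path for message
# passing. Nodes are spots in embedding row order; edges carry the
# embedding-space Euclidean distance. Exact O(n^2) search: inputs here are
# a few thousand spots at most, where exactness beats indexing.

new_graph <- function(nbr, dist, ids, k_num, pruned = FALSE) {
  structure(
    list(n = length(nbr), nbr = nbr, dist = dist, ids = ids,
         k_num = k_num, pruned = pruned, undirected = TRUE),
    class = "mpmim_graph"
  )
}

#' Build the k-nearest-neighbour graph of an embedding
#'
#' Links every spot to its `k_num` nearest spots by embedding-space
#' Euclidean distance and symmetrizes the edge set by union (an edge is kept
#' if either endpoint selected the other), so the graph is undirected and
#' node degrees range from `k_num` up to at most `n - 1`. Distance ties are
#' broken by ascending spot index.
#'
#' @param embedding Embedding tibble.
#' @param k_num Neighbours per node, `1 <= k_num <= n - 1`.
#' @return An object of class `mpmim_graph` with per-node neighbour index
#'   and distance lists.
#' @examples
#' emb <- tibble::tibble(spot = c("a", "b", "c"), d1 = c(0, 1, 10))
#' g <- knn_graph(emb, k_num = 1)
#' g$nbr  # union symmetrization gives b both a and c
#' @export
knn_graph <- function(embedding, k_num) {
  mat <- embedding_matrix(embedding)
  n <- nrow(mat)
  k_num <- check_count(k_num, "k_num", min = 1L)
  if (k_num > n - 1L) {
    abort(sprintf("k_num = %d out of range: must be <= n - 1 = %d.",
                  k_num, n - 1L))
  }
  D <- as.matrix(dist(mat))
  sel <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    sel[i, order(d)[seq_len(k_num)]] <- TRUE  # order() is stable: ties fall to the lower index
  }
  sel <- sel | t(sel)
  nbr <- lapply(seq_len(n), function(i) which(sel[i, ]))
  dst <- lapply(seq_len(n), function(i) unname(D[i, nbr[[i]]]))
  new_graph(nbr, dst, rownames(mat), k_num)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Prune outlier neighbours from a KNN graph
#'
#' For each node, neighbours whose distance exceeds that node's mean + 1 sd
#' of neighbour distances are removed; the single nearest neighbour is
#' always retained, so no node is isolated. Symmetry is re-established by
#' union afterwards (an edge survives if either endpoint kept it). Applied
#' once; this yields an adaptive per-node neighbourhood size.
#'
#' @param g An `mpmim_graph`.
#' @return The pruned `mpmim_graph`.
#' @export
prune_graph <- function(g) {
  stopifnot(inherits(g, "mpmim_graph"))
  n <- g$n
  keep <- vector("list", n)
  for (i in seq_len(n)) {
    d <- g$dist[[i]]
    if (length(d) <= 1L) {
      keep[[i]] <- g$nbr[[i]]
      next
    }
    thr <- mean(d) + pop_sd(d)
    ok <- d <= thr
    ok[which.min(d)] <- TRUE  # nearest always kept; which.min ties -> lower index
    keep[[i]] <- g$nbr[[i]][ok]
  }
  sel <- matrix(FALSE, n, n)
  for (i in seq_len(n)) sel[i, keep[[i]]] <- TRUE
  sel <- sel | t(sel)
  nbr <- vector("list", n)
  dst <- vector("list", n)
  for (i in seq_len(n)) {
    js <- which(sel[i, ])
    nbr[[i]] <- js
    dst[[i]] <- g$dist[[i]][match(js, g$nbr[[i]])]
  }
  new_graph(nbr, dst, g$ids, g$k_num, pruned = TRUE)
}

#' Adjacency matrix of a neighbour graph
#'
#' @param g An `mpmim_graph`.
#' @param weighted If `TRUE`, entries are embedding-space distances instead
#'   of 0/1.
#' @return A sparse symmetric `Matrix` with zero diagonal, spot ids as
#'   dimnames.
#' @export
graph_adjacency <- function(g, weighted = FALSE) {
  stopifnot(inherits(g, "mpmim_graph"))
  ii <- rep.int(seq_len(g$n), lengths(g$nbr))
  jj <- unlist(g$nbr, use.names = FALSE)
  xx <- if (weighted) unlist(g$dist, use.names = FALSE) else rep(1, length(jj))
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(g$n, g$n),
                       dimnames = list(g$ids, g$ids))
}

#' Edge list of a neighbour graph
#'
#' One row per directed incidence (`i < j` kept once since the graph is
#' undirected), handy for writing an inspection TSV.
#'
#' @param g An `mpmim_graph`.
#' @return Tibble with columns `from`, `to`, `distance`.
#' @export
graph_edges <- function(g) {
  stopifnot(inherits(g, "mpmim_graph"))
  ii <- rep.int(seq_len(g$n), lengths(g$nbr))
  jj <- unlist(g$nbr, use.names = FALSE)
  dd <- unlist(g$dist, use.names = FALSE)
  up <- ii < jj
  tibble(from = g$ids[ii[up]], to = g$ids[jj[up]], distance = dd[up])
}

#' @export
print.mpmim_graph <- function(x, ...) {
  deg <- lengths(x$nbr)
  cat(sprintf("<mpmim_graph> %d nodes, %d undirected edges, degree %d-%d (k_num = %d%s)\n",
              x$n, sum(deg) / 2, min(deg), max(deg), x$k_num,
              if (x$pruned) ", pruned" else ""))
  invisible(x)
}
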