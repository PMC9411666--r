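# Independent brute-force oracles: plain double loops and pair
# enumeration, no matrix algebra, kept deliberately separate from the
# package's implementations.

oracle_morans_i <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  s0 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + W[i, j] * z[i] * z[j]
      s0 <- s0 + W[i, j]
    }
  }
  n * num / (s0 * sum(z^2))
}

oracle_gearys_c <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  s0 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + W[i, j] * (x[i] - x[j])^2
      s0 <- s0 + W[i, j]
    }
  }
  (n - 1) * num / (2 * s0 * sum(z^2))
}

# pair-counting ARI: enumerate all C(n,2) spot pairs and classify agreement
oracle_ari <- function(a, b) {
  n <- length(a)
  ss <- 0  # together in both
  sd_ <- 0 # together in a only
  ds <- 0  # together in b only
  dd <- 0  # apart in both
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) ss <- ss + 1
      else if (sa) sd_ <- sd_ + 1
      else if (sb) ds <- ds + 1
      else dd <- dd + 1
    }
  }
  tot <- ss + sd_ + ds + dd
  exp_ss <- (ss + sd_) * (ss + ds) / tot
  max_ss <- ((ss + sd_) + (ss + ds)) / 2
  if (max_ss == exp_ss) return(1)
  (ss - exp_ss) / (max_ss - exp_ss)
}

# nearest neighbours of row i by scanning all pairwise distances
oracle_knn <- function(mat, i, k) {
  d <- sqrt(colSums((t(mat) - mat[i, ])^2))
  d[i] <- Inf
  order(d)[seq_len(k)]
}

dense_weight_matrix <- function(sw) as.matrix(sw$w)

# small random spot layouts with unique ids
random_coords <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(spot = sprintf("r%03d", seq_len(n)),
                 x = stats::runif(n, 0, 10), y = stats::runif(n, 0, 10))
}

random_field <- function(n, seed) {
  set.seed(seed)
  stats::rnorm(n)
}

# 4x4 checkerboard on the integer grid with rook (radius 1) weights:
# the canonical perfect-negative-autocorrelation instance
checkerboard_fixture <- function() {
  xy <- make_lattice(4, 4, "square")
  vals <- (-1)^(xy$x + xy$y)
  list(coords = xy, values = vals, sw = radius_weights(xy, 1))
}
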