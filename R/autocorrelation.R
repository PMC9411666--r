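# Global spatial autocorrelation of embedding dimensions under binary
# spatial weight matrices. Weights are 0/1 and the statistics normalise by
# S0 = sum of all weights (no row standardisation).

new_spatial_weights <- function(w, scheme, parameter, ids) {
  # general (not symmetric-storage) sparse form so triplet extraction sees
  # every nonzero entry
  w <- methods::as(methods::as(w, "generalMatrix"), "CsparseMatrix")
  structure(list(w = w, scheme = scheme, parameter = parameter,
                 ids = ids, n = nrow(w), S0 = sum(w)),
            class = "mpmim_spatial_weights")
}

#' @export
print.mpmim_spatial_weights <- function(x, ...) {
  cat(sprintf("<mpmim_spatial_weights> %d spots, %s scheme (%s = %g), S0 = %g\n",
              x$n, x$scheme,
              if (x$scheme == "radius") "radius" else "k",
              x$parameter, x$S0))
  invisible(x)
}

#' Radius-distance spatial weight matrix
#'
#' `w_ij = 1` when the spatial Euclidean distance satisfies
#' `0 < d_ij <= radius`, else 0. Symmetric with zero diagonal by
#' construction. `radius = "auto"` picks the smallest radius giving every
#' spot at least one neighbour: the maximum over spots of the
#' nearest-neighbour distance.
#'
#' @param coords Coordinates tibble (`spot`, `x`, `y`).
#' @param radius Positive number or `"auto"`.
#' @return An `mpmim_spatial_weights` object.
#' @examples
#' xy <- tibble::tibble(spot = letters[1:4], x = 0:3, y = 0)
#' radius_weights(xy, 1)$S0  # path graph: 6 directed pairs
#' @export
radius_weights <- function(coords, radius = "auto") {
  xy <- coordinate_matrix(coords)
  D <- as.matrix(dist(xy))
  if (identical(radius, "auto")) {
    diag(D) <- Inf
    radius <- max(apply(D, 1L, min))
    diag(D) <- 0
  } else if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    abort("`radius` must be a positive number or \"auto\".")
  }
  w <- Matrix::Matrix((D > 0 & D <= radius) * 1, sparse = TRUE)
  dimnames(w) <- list(rownames(xy), rownames(xy))
  if (sum(w) == 0) {
    abort(sprintf("radius %g leaves every spot isolated (S0 = 0); try radius = \"auto\".",
                  radius))
  }
  new_spatial_weights(w, "radius", radius, rownames(xy))
}

#' Spatial KNN weight matrix
#'
#' Each spot is linked to its `k` nearest spots by spatial Euclidean
#' distance; the binary weights are symmetrized by union. Distance ties are
#' broken by ascending spot index.
#'
#' @param coords Coordinates tibble (`spot`, `x`, `y`).
#' @param k Neighbour count, `1 <= k <= n - 1`.
#' @return An `mpmim_spatial_weights` object.
#' @export
knn_weights <- function(coords, k = 6L) {
  xy <- coordinate_matrix(coords)
  n <- nrow(xy)
  k <- check_count(k, "k", min = 1L)
  if (k > n - 1L) abort(sprintf("k = %d out of range: must be <= n - 1 = %d.", k, n - 1L))
  D <- as.matrix(dist(xy))
  sel <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    sel[i, order(d)[seq_len(k)]] <- TRUE
  }
  sel <- sel | t(sel)
  w <- Matrix::Matrix(sel * 1, sparse = TRUE)
  dimnames(w) <- list(rownames(xy), rownames(xy))
  new_spatial_weights(w, "knn", k, rownames(xy))
}

#' Build a spatial weight matrix from a configuration
#'
#' Dispatches to [radius_weights()] or [knn_weights()] according to
#' `config$weight_type`.
#'
#' @param coords Coordinates tibble.
#' @param config An [mpmim_config()].
#' @return An `mpmim_spatial_weights` object.
#' @export
spatial_weights <- function(coords, config = mpmim_config()) {
  stopifnot(inherits(config, "mpmim_config"))
  switch(config$weight_type,
    radius = radius_weights(coords, config$radius),
    knn = knn_weights(coords, config$knn_w)
  )
}

check_field <- function(x, sw) {
  x <- as.numeric(x)
  if (length(x) != sw$n) {
    abort(sprintf("value vector has length %d but the weight matrix covers %d spots.",
                  length(x), sw$n))
  }
  if (!all(is.finite(x))) abort("non-finite values in the field.")
  x
}

#' Global Moran's I of one embedding dimension
#'
#' `I = n * sum_ij w_ij (x_i - xbar)(x_j - xbar) / (S0 * sum_i (x_i - xbar)^2)`
#' with binary weights `w_ij`. Values near 1 indicate strong positive
#' spatial autocorrelation (similar values cluster in space), near -1
#' strong negative autocorrelation, near 0 spatial randomness; under random
#' permutation the expectation is `-1/(n-1)`.
#'
#' @param x Numeric vector, one value per spot in weight-matrix order.
#' @param sw An `mpmim_spatial_weights` object.
#' @return A single number, or `NA` with a warning when `x` has zero
#'   variance (the statistic is undefined for a constant field).
#' @export
morans_i <- function(x, sw) {
  stopifnot(inherits(sw, "mpmim_spatial_weights"))
  x <- check_field(x, sw)
  z <- x - mean(x)
  denom <- sum(z^2)
  if (denom == 0) {
    warn("Moran's I undefined for a constant field; returning NA.")
    return(NA_real_)
  }
  cross <- as.numeric(Matrix::crossprod(z, sw$w %*% z))
  sw$n * cross / (sw$S0 * denom)
}

#' Global Geary's C of one embedding dimension (reported as 1 - C)
#'
#' `C = (n-1) * sum_ij w_ij (x_i - x_j)^2 / (2 * S0 * sum_i (x_i - xbar)^2)`
#' lies in `[0, 2]` with 0 = perfect positive and 2 = perfect negative
#' autocorrelation. The returned value is `1 - C`, matching Moran's I sign
#' convention (1 positive, -1 negative, 0 none); set `transformed = FALSE`
#' for raw C.
#'
#' @inheritParams morans_i
#' @param transformed Return `1 - C` (default) rather than raw C.
#' @return A single number, or `NA` with a warning for a constant field.
#' @export
gearys_c <- function(x, sw, transformed = TRUE) {
  stopifnot(inherits(sw, "mpmim_spatial_weights"))
  x <- check_field(x, sw)
  z <- x - mean(x)
  denom <- sum(z^2)
  if (denom == 0) {
    warn("Geary's C undefined for a constant field; returning NA.")
    return(NA_real_)
  }
  trip <- methods::as(sw$w, "TsparseMatrix")
  num <- sum(trip@x * (x[trip@i + 1L] - x[trip@j + 1L])^2)
  gc <- (sw$n - 1) * num / (2 * sw$S0 * denom)
  if (transformed) 1 - gc else gc
}

#' Score an embedding by filtered spatial autocorrelation
#'
#' Computes the chosen statistic for every embedding dimension under the
#' given spatial weight matrix, then reduces across dimensions with
#' maximum (default), average or minimum filtering. Zero-variance
#' dimensions are undefined and excluded from the reduction (with a
#' warning); an embedding whose dimensions are all constant is an error.
#'
#' @param embedding Embedding tibble, spot order matching the weight matrix.
#' @param sw An `mpmim_spatial_weights` object.
#' @param statistic `"moran"` or `"geary"` (the latter reported as 1 - C).
#' @param filter_type `"max"`, `"avg"` or `"min"`.
#' @param name Optional embedding label stored with the score.
#' @return An `mpmim_score` object: per-dimension values plus the filtered
#'   score. `tidy()` returns the per-dimension table, `glance()` the
#'   one-row summary.
#' @export
score_embedding <- function(embedding, sw,
                            statistic = c("moran", "geary"),
                            filter_type = c("max", "avg", "min"),
                            name = NULL) {
  statistic <- match.arg(statistic)
  filter_type <- match.arg(filter_type)
  mat <- embedding_matrix(embedding)
  if (nrow(mat) != sw$n) {
    abort(sprintf("embedding has %d spots but the weight matrix covers %d.",
                  nrow(mat), sw$n))
  }
  stat_fun <- if (statistic == "moran") morans_i else gearys_c
  vals <- vapply(seq_len(ncol(mat)), function(d) {
    if (sd(mat[, d]) == 0) return(NA_real_)
    stat_fun(mat[, d], sw)
  }, numeric(1))
  defined <- !is.na(vals)
  if (!any(defined)) {
    abort("all embedding dimensions have zero variance; the score is undefined.")
  }
  if (any(!defined)) {
    warn(sprintf("%d zero-variance dimension(s) excluded from %s filtering: %s",
                 sum(!defined), filter_type,
                 paste(colnames(mat)[!defined], collapse = ", ")))
  }
  filtered <- switch(filter_type,
    max = max(vals[defined]),
    avg = mean(vals[defined]),
    min = min(vals[defined])
  )
  structure(
    list(
      name = name %||% "embedding",
      dimensions = tibble(dimension = colnames(mat), value = vals,
                          defined = defined),
      score = filtered,
      statistic = statistic, filter_type = filter_type,
      scheme = sw$scheme, parameter = sw$parameter, n_spots = sw$n
    ),
    class = "mpmim_score"
  )
}

#' @export
print.mpmim_score <- function(x, ...) {
  cat(sprintf("<mpmim_score> %s: %s-filtered %s = %.4f over %d dimension(s) (%s weights)\n",
              x$name, x$filter_type,
              if (x$statistic == "moran") "Moran's I" else "1 - Geary's C",
              x$score, sum(x$dimensions$defined), x$scheme))
  invisible(x)
}

#' @rdname score_embedding
#' @param x An `mpmim_score` object.
#' @param ... Unused.
#' @method tidy mpmim_score
#' @export
tidy.mpmim_score <- function(x, ...) {
  dplyr::mutate(x$dimensions, name = x$name, statistic = x$statistic,
                .before = 1L)
}

#' @rdname score_embedding
#' @method glance mpmim_score
#' @export
glance.mpmim_score <- function(x, ...) {
  tibble(name = x$name, score = x$score, statistic = x$statistic,
         filter_type = x$filter_type, scheme = x$scheme,
         parameter = x$parameter, n_spots = x$n_spots,
         n_dims = nrow(x$dimensions),
         n_defined = sum(x$dimensions$defined))
}
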