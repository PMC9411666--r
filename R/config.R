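#' Analysis configuration
#'
#' Bundles the hyperparameters shared by the transform/score/rank pipeline.
#' The two message-passing flavours come with their own conventional graph
#' sizes: distance-softmax aggregation defaults to `k_num = 90` while basic
#' (uniform-weight) graph convolution defaults to `k_num = 9`; both default to
#' `l_num = 15` stacked layers. Unless a spatial weight scheme is requested
#' explicitly, the distance flavour is paired with the radius scheme and the
#' basic flavour with the spatial-KNN scheme.
#'
#' @param k_num Number of nearest neighbours for the embedding-space graph
#'   used by message passing. Defaults to 90 for `mp_type = "distance"` and
#'   9 for `mp_type = "basic"`.
#' @param l_num Number of stacked message-passing layers (0 = no transform).
#' @param mp_type Aggregation weights: `"distance"` (softmax of embedding
#'   Euclidean distances, favouring long-range neighbours) or `"basic"`
#'   (uniform weights).
#' @param weight_type Spatial weight matrix scheme for the autocorrelation
#'   statistic: `"radius"` or `"knn"`. `NULL` (default) derives it from
#'   `mp_type` as described above.
#' @param filter_type Reduction across embedding dimensions: `"max"`
#'   (default), `"avg"` or `"min"`.
#' @param statistic Autocorrelation statistic: `"moran"` or `"geary"`
#'   (reported as 1 - C so its sign matches Moran's I).
#' @param radius Radius for the radius weight scheme (same units as the
#'   coordinates), or `"auto"` to use the largest nearest-neighbour distance
#'   so every spot has at least one neighbour.
#' @param knn_w Neighbour count for the spatial KNN weight scheme. Default 6,
#'   the first hexagonal neighbour ring of a Visium array.
#' @param prune Whether to prune embedding-graph neighbour lists by the
#'   per-node mean + 1 sd distance rule before message passing.
#' @param include_self Whether a node's own feature participates in its
#'   neighbourhood aggregation. Default `FALSE`: the update is a pure
#'   neighbour average.
#' @param overflow_guard Per-node fallback threshold for the distance
#'   softmax: nodes whose largest neighbour distance exceeds this value use
#'   uniform weights instead, keeping `exp()` finite. Default 700, just
#'   under the double-precision overflow bound of `exp`.
#' @param seed Integer seed for the randomized steps (K-means restarts).
#' @param verbose Emit progress messages to stderr.
#'
#' @return A list of class `mpmim_config`.
#' @examples
#' mpmim_config()
#' mpmim_config(mp_type = "basic")$k_num  # 9
#' @export
mpmim_config <- function(k_num = NULL,
                         l_num = 15,
                         mp_type = c("distance", "basic"),
                         weight_type = NULL,
                         filter_type = c("max", "avg", "min"),
                         statistic = c("moran", "geary"),
                         radius = "auto",
                         knn_w = 6L,
                         prune = TRUE,
                         include_self = FALSE,
                         overflow_guard = 700,
                         seed = 1L,
                         verbose = FALSE) {
  mp_type <- match.arg(mp_type)
  filter_type <- match.arg(filter_type)
  statistic <- match.arg(statistic)
  if (is.null(k_num)) k_num <- if (mp_type == "distance") 90L else 9L
  if (is.null(weight_type)) {
    weight_type <- if (mp_type == "distance") "radius" else "knn"
  }
  weight_type <- match.arg(weight_type, c("radius", "knn"))

  k_num <- check_count(k_num, "k_num", min = 1L)
  l_num <- check_count(l_num, "l_num", min = 0L)
  knn_w <- check_count(knn_w, "knn_w", min = 1L)
  if (!identical(radius, "auto")) {
    if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
        radius <= 0) {
      abort("`radius` must be a positive number or \"auto\".")
    }
    radius <- as.numeric(radius)
  }
  if (!is.numeric(overflow_guard) || overflow_guard <= 0) {
    abort("`overflow_guard` must be a positive number.")
  }

  structure(
    list(
      k_num = k_num, l_num = l_num, mp_type = mp_type,
      weight_type = weight_type, filter_type = filter_type,
      statistic = statistic, radius = radius, knn_w = knn_w,
      prune = isTRUE(prune), include_self = isTRUE(include_self),
      overflow_guard = as.numeric(overflow_guard),
      seed = as.integer(seed), verbose = isTRUE(verbose)
    ),
    class = "mpmim_config"
  )
}

#' @export
print.mpmim_config <- function(x, ...) {
  cat("<mpmim_config>\n")
  cat(sprintf("  message passing: %s, k_num = %d, l_num = %d%s\n",
              x$mp_type, x$k_num, x$l_num,
              if (x$prune) " (pruned graph)" else ""))
  cat(sprintf("  scoring: %s, %s weights (%s), %s filtering\n",
              x$statistic, x$weight_type,
              if (x$weight_type == "radius") {
                if (identical(x$radius, "auto")) "radius = auto"
                else sprintf("radius = %g", x$radius)
              } else sprintf("k = %d", x$knn_w),
              x$filter_type))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

log_msg <- function(verbose, ...) {
  if (isTRUE(verbose)) inform(sprintf(...))
  invisible(NULL)
}
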