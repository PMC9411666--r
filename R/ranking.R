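# Rank a collection of candidate embeddings by transformed, filtered
# spatial autocorrelation, and evaluate rankings against a ground truth
# derived from expert annotations via K-means + adjusted Rand index.

check_embedding_list <- function(embeddings) {
  if (!is.list(embeddings) || length(embeddings) < 1L ||
      !all(vapply(embeddings, is.data.frame, logical(1)))) {
    abort("`embeddings` must be a non-empty named list of embedding tibbles.")
  }
  nms <- names(embeddings)
  if (is.null(nms) || anyNA(nms) || any(nms == "") || anyDuplicated(nms)) {
    abort("`embeddings` must have unique, non-empty names.")
  }
  invisible(nms)
}

#' Rank candidate embeddings by transformed spatial autocorrelation
#'
#' The core pipeline: every embedding is transformed by stacked message
#' passing ([mp_transform()]), scored by the filtered autocorrelation
#' statistic ([score_embedding()]) under a spatial weight matrix built once
#' from the coordinates, and the embeddings are sorted by descending score
#' (rank 1 = best). Score ties are broken by ascending embedding name so
#' ranking is deterministic and invariant to input order.
#'
#' @param embeddings Named list of embedding tibbles sharing the
#'   coordinates' spot set.
#' @param coords Coordinates tibble (`spot`, `x`, `y`).
#' @param config An [mpmim_config()].
#' @return An `mpmim_ranking` object. `tidy()` returns the per-embedding
#'   table (`name`, `score`, `rank`), `glance()` a one-row summary of the
#'   configuration used.
#' @examples
#' xy <- make_lattice(8, 8)
#' suite <- make_suite(xy, m = 3, seed = 1)
#' rank_embeddings(suite$embeddings, xy,
#'                 mpmim_config(k_num = 10, l_num = 2))
#' @export
rank_embeddings <- function(embeddings, coords, config = mpmim_config()) {
  check_embedding_list(embeddings)
  stopifnot(inherits(config, "mpmim_config"))
  coord_ids <- as.character(coords$spot)
  bad <- names(embeddings)[!vapply(embeddings, function(e) {
    setequal(as.character(e$spot), coord_ids)
  }, logical(1))]
  if (length(bad) > 0) {
    abort(sprintf("embedding(s) with a spot set differing from the coordinates: %s",
                  paste(bad, collapse = ", ")))
  }
  sw <- spatial_weights(coords, config)
  scores <- purrr::imap_dbl(embeddings, function(emb, nm) {
    emb <- emb[match(coord_ids, as.character(emb$spot)), , drop = FALSE]
    log_msg(config$verbose, "transforming and scoring %s", nm)
    tr <- mp_transform(emb, config)
    score_embedding(tr, sw, config$statistic, config$filter_type,
                    name = nm)$score
  })
  ord <- order(-scores, names(scores))
  res <- tibble(name = names(scores)[ord], score = unname(scores[ord]),
                rank = seq_along(scores))
  structure(list(ranking = res, config = config,
                 scheme = sw$scheme, parameter = sw$parameter,
                 n_spots = sw$n),
            class = "mpmim_ranking")
}

#' @export
print.mpmim_ranking <- function(x, ...) {
  cat(sprintf("<mpmim_ranking> %d embeddings, %d spots; %s/%s filter, k_num = %d, l_num = %d\n",
              nrow(x$ranking), x$n_spots, x$config$statistic,
              x$config$filter_type, x$config$k_num, x$config$l_num))
  print(x$ranking, n = 10)
  invisible(x)
}

#' @rdname rank_embeddings
#' @param x An `mpmim_ranking` object.
#' @param ... Unused.
#' @method tidy mpmim_ranking
#' @export
tidy.mpmim_ranking <- function(x, ...) x$ranking

#' @rdname rank_embeddings
#' @method glance mpmim_ranking
#' @export
glance.mpmim_ranking <- function(x, ...) {
  tibble(n_embeddings = nrow(x$ranking), n_spots = x$n_spots,
         statistic = x$config$statistic, filter_type = x$config$filter_type,
         mp_type = x$config$mp_type, k_num = x$config$k_num,
         l_num = x$config$l_num, scheme = x$scheme, parameter = x$parameter,
         best = x$ranking$name[1L], best_score = x$ranking$score[1L])
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same spots,
#' computed from the contingency table:
#' `ARI = (sum_ij C(n_ij,2) - E) / (0.5 * (A + B) - E)` with
#' `A = sum_i C(a_i,2)`, `B = sum_j C(b_j,2)` and `E = A * B / C(n,2)`.
#' 1 = identical partitions (up to relabeling), ~0 = chance agreement.
#'
#' @param a,b Vectors of labels (any atomic type), same length and order.
#' @return A single number in `[-1, 1]`.
#' @examples
#' ari(c(1, 1, 2, 2), c("x", "x", "y", "y"))  # 1
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) {
    abort(sprintf("partitions differ in length: %d vs %d.",
                  length(a), length(b)))
  }
  n <- length(a)
  if (n < 2L) abort("need at least two spots to compare partitions.")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  A <- sum(comb2(rowSums(tab)))
  B <- sum(comb2(colSums(tab)))
  expected <- A * B / comb2(n)
  max_index <- (A + B) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Ground-truth ranking of embeddings by K-means ARI
#'
#' Clusters every embedding with K-means (cluster count = number of
#' distinct ground-truth labels, 10 random restarts under a fixed seed),
#' computes the ARI of the clustering against the labels, and ranks the
#' embeddings by descending ARI. This ordering is the reference against
#' which a predicted ranking is judged.
#'
#' @param embeddings Named list of embedding tibbles.
#' @param labels Labels tibble (`spot`, `label`) covering every spot.
#' @param seed Integer seed for the K-means restarts.
#' @param nstart Number of K-means restarts. Default 10.
#' @return Tibble with columns `name`, `ari`, `rank` (1 = highest ARI;
#'   ties broken by ascending name).
#' @export
ground_truth_ranking <- function(embeddings, labels, seed = 1L, nstart = 10L) {
  check_embedding_list(embeddings)
  lv <- label_vector(labels)
  k <- length(unique(lv))
  if (k < 2L) abort("need at least two distinct ground-truth labels.")
  aris <- purrr::imap_dbl(embeddings, function(emb, nm) {
    mat <- embedding_matrix(emb)
    missing <- setdiff(rownames(mat), names(lv))
    if (length(missing) > 0) {
      abort(sprintf("labels missing for %d spot(s) of %s (e.g. %s).",
                    length(missing), nm, missing[1L]))
    }
    if (nrow(mat) < k) abort(sprintf("%s has fewer spots than clusters.", nm))
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    cl <- kmeans(mat, centers = k, nstart = nstart)$cluster
    ari(cl, lv[rownames(mat)])
  })
  ord <- order(-aris, names(aris))
  tibble(name = names(aris)[ord], ari = unname(aris[ord]),
         rank = seq_along(aris))
}

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Spearman rank correlation between two rankings
#'
#' Correlation of tie-averaged ranks (equivalent to the classical
#' `1 - 6 * sum(d^2) / (n (n^2 - 1))` when there are no ties), with a
#' two-sided p-value from the large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Because only agreement with a reference ordering is of interest, a
#' clamped value `max(rho, 0)` is also reported.
#'
#' @param x,y Either numeric vectors (scores or ranks, same item order) or
#'   data frames with columns `name` and `rank`, matched by name.
#' @return One-row tibble: `rho`, `p_value`, `rho_clamped`, `n`.
#' @examples
#' spearman_rank(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))  # rho = 0.8
#' @export
spearman_rank <- function(x, y) {
  if (is.data.frame(x) && is.data.frame(y)) {
    for (df in list(x, y)) {
      if (!all(c("name", "rank") %in% names(df))) {
        abort("ranking data frames need columns `name` and `rank`.")
      }
    }
    if (!setequal(x$name, y$name) || anyDuplicated(x$name) ||
        anyDuplicated(y$name)) {
      abort("rankings must cover the same set of unique names.")
    }
    y <- y[match(x$name, y$name), , drop = FALSE]
    x <- x$rank
    y <- y$rank
  }
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) abort("rankings differ in length.")
  n <- length(x)
  if (n < 3L) abort("need at least three items for a rank correlation.")
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort("a ranking with all-tied items has no defined correlation.")
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  tibble(rho = rho, p_value = p, rho_clamped = max(rho, 0), n = n)
}

#' Per-dimension autocorrelation baselines
#'
#' The reference comparison: rank the *untransformed* embeddings by the
#' autocorrelation statistic of each single dimension in turn, and measure
#' each such ranking against the ground-truth (ARI) ranking with Spearman
#' correlation. The best-performing dimension is the baseline an aggregate
#' method must beat.
#'
#' @param embeddings Named list of embedding tibbles (all with the same
#'   dimension count).
#' @param coords Coordinates tibble.
#' @param labels Labels tibble.
#' @param statistic `"moran"` or `"geary"` (as 1 - C, so signs compare).
#' @param config An [mpmim_config()]; supplies the spatial weight scheme
#'   and the K-means seed.
#' @return An `mpmim_baseline` object: `per_dimension` tibble (`dimension`,
#'   `rho`, `p_value`, `rho_clamped`) plus `best` (the highest-rho row) and
#'   the ground-truth ranking used. `tidy()` returns the per-dimension
#'   table; `glance()` the best row.
#' @export
baseline_per_dimension <- function(embeddings, coords, labels,
                                   statistic = c("moran", "geary"),
                                   config = mpmim_config()) {
  statistic <- match.arg(statistic)
  check_embedding_list(embeddings)
  n_dims <- unique(vapply(embeddings, function(e) ncol(e) - 1L, integer(1)))
  if (length(n_dims) != 1L) {
    abort("all embeddings must have the same number of dimensions.")
  }
  coord_ids <- as.character(coords$spot)
  sw <- spatial_weights(coords, config)
  truth <- ground_truth_ranking(embeddings, labels, seed = config$seed)
  stat_fun <- if (statistic == "moran") morans_i else gearys_c
  per_dim <- purrr::map_dfr(seq_len(n_dims), function(d) {
    vals <- purrr::imap_dbl(embeddings, function(emb, nm) {
      mat <- embedding_matrix(emb)[coord_ids, , drop = FALSE]
      x <- mat[, d]
      if (sd(x) == 0) return(NA_real_)
      stat_fun(x, sw)
    })
    if (anyNA(vals)) {
      return(tibble(dimension = d, rho = NA_real_, p_value = NA_real_,
                    rho_clamped = NA_real_))
    }
    ord <- order(-vals, names(vals))
    pred <- tibble(name = names(vals)[ord], rank = seq_along(vals))
    sp <- spearman_rank(pred, truth[, c("name", "rank")])
    tibble(dimension = d, rho = sp$rho, p_value = sp$p_value,
           rho_clamped = sp$rho_clamped)
  })
  defined <- per_dim[!is.na(per_dim$rho), , drop = FALSE]
  if (nrow(defined) == 0L) abort("no dimension yielded a defined baseline.")
  best <- defined[which.max(defined$rho), , drop = FALSE]
  structure(list(per_dimension = per_dim, best = best, truth = truth,
                 statistic = statistic),
            class = "mpmim_baseline")
}

#' @export
print.mpmim_baseline <- function(x, ...) {
  cat(sprintf("<mpmim_baseline> %s per-dimension baselines; best: dimension %d, rho = %.3f\n",
              x$statistic, x$best$dimension, x$best$rho))
  print(x$per_dimension)
  invisible(x)
}

#' @rdname baseline_per_dimension
#' @param x An `mpmim_baseline` object.
#' @param ... Unused.
#' @method tidy mpmim_baseline
#' @export
tidy.mpmim_baseline <- function(x, ...) x$per_dimension

#' @rdname baseline_per_dimension
#' @method glance mpmim_baseline
#' @export
glance.mpmim_baseline <- function(x, ...) {
  tibble(statistic = x$statistic, best_dimension = x$best$dimension,
         best_rho = x$best$rho, best_rho_clamped = x$best$rho_clamped)
}

#' Top-k report of a predicted ranking against the ground truth
#'
#' Lists the k best embeddings of a predicted ranking alongside their ARI
#' and ground-truth rank, and flags whether the ground-truth best embedding
#' made it into the predicted top k — the practical success criterion when
#' a handful of candidate embeddings is carried forward.
#'
#' @param ranking An `mpmim_ranking` or a tibble with `name` and `rank`.
#' @param truth Ground-truth ranking tibble from [ground_truth_ranking()]
#'   (columns `name`, `ari`, `rank`).
#' @param k Number of top embeddings to report. Default 5.
#' @return Tibble with columns `name`, `predicted_rank`, `score` (if
#'   available), `ari`, `truth_rank`; attribute `contains_truth_best`
#'   (logical) answers the top-k hit question, also exposed by message.
#' @export
top_k_report <- function(ranking, truth, k = 5L) {
  pred <- if (inherits(ranking, "mpmim_ranking")) ranking$ranking else ranking
  if (!all(c("name", "rank") %in% names(pred))) {
    abort("`ranking` needs columns `name` and `rank`.")
  }
  if (!all(c("name", "rank") %in% names(truth))) {
    abort("`truth` needs columns `name` and `rank`.")
  }
  k <- check_count(k, "k", min = 1L)
  m <- nrow(pred)
  if (k > m) abort(sprintf("k = %d exceeds the number of embeddings (%d).", k, m))
  if (!setequal(pred$name, truth$name)) {
    abort("predicted and ground-truth rankings cover different embeddings.")
  }
  top <- pred[order(pred$rank), , drop = FALSE][seq_len(k), , drop = FALSE]
  idx <- match(top$name, truth$name)
  out <- tibble(name = top$name, predicted_rank = top$rank)
  if ("score" %in% names(top)) out$score <- top$score
  if ("ari" %in% names(truth)) out$ari <- truth$ari[idx]
  out$truth_rank <- truth$rank[idx]
  best_name <- truth$name[truth$rank == 1L][1L]
  attr(out, "contains_truth_best") <- best_name %in% out$name
  out
}
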