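# Tabular contracts shared by every stage.
#
# An *embedding* is a tibble whose first column (default "spot") holds unique
# spot identifiers and whose remaining columns are numeric latent dimensions.
# *Coordinates* are a tibble with columns spot, x, y. *Labels* are a tibble
# with columns spot, label. Row order of the embedding is canonical: every
# graph, weight matrix and statistic indexes spots in that order.

#' Extract the numeric matrix of an embedding tibble
#'
#' Validates the embedding contract (unique ids, all-numeric finite values,
#' at least two spots and one dimension) and returns the spots x dimensions
#' matrix with spot ids as row names.
#'
#' @param embedding Embedding tibble: id column plus numeric dimensions.
#' @param id_column Name of the identifier column. Default `"spot"`.
#' @return Numeric matrix, `rownames` = spot ids.
#' @export
embedding_matrix <- function(embedding, id_column = "spot") {
  if (!is.data.frame(embedding)) abort("`embedding` must be a data frame.")
  if (!id_column %in% names(embedding)) {
    abort(sprintf("embedding has no id column `%s`.", id_column))
  }
  ids <- as.character(embedding[[id_column]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate spot ids in embedding: %s",
                  paste(head(dup, 5L), collapse = ", ")))
  }
  if (anyNA(ids) || any(ids == "")) abort("missing or empty spot ids.")
  vals <- embedding[setdiff(names(embedding), id_column)]
  if (ncol(vals) < 1L) abort("embedding needs at least one dimension.")
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(sprintf("non-numeric embedding column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  m <- as.matrix(vals)
  if (nrow(m) < 2L) abort("embedding needs at least two spots.")
  if (!all(is.finite(m))) {
    ij <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    abort(sprintf("non-finite embedding value at row %d (spot %s), column %s.",
                  ij[1L], ids[ij[1L]], colnames(m)[ij[2L]]))
  }
  rownames(m) <- ids
  m
}

as_embedding_tibble <- function(mat, ids = rownames(mat),
                                dims = colnames(mat)) {
  if (is.null(dims)) dims <- paste0("dim", seq_len(ncol(mat)))
  out <- as_tibble(as.data.frame(mat), .name_repair = "minimal")
  names(out) <- dims
  dplyr::bind_cols(tibble(spot = as.character(ids)), out)
}

coordinate_matrix <- function(coords) {
  if (!is.data.frame(coords)) abort("`coords` must be a data frame.")
  need <- c("spot", "x", "y")
  if (!all(need %in% names(coords))) {
    abort("`coords` must have columns spot, x, y.")
  }
  extra_dims <- intersect(c("z"), names(coords))
  if (length(extra_dims) > 0) {
    abort("coordinates must be 2-D (x, y); higher dimensions are not supported.")
  }
  ids <- as.character(coords$spot)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate spot ids in coordinates: %s",
                  paste(head(unique(ids[duplicated(ids)]), 5L),
                        collapse = ", ")))
  }
  xy <- cbind(x = as.numeric(coords$x), y = as.numeric(coords$y))
  if (!all(is.finite(xy))) abort("non-finite coordinate values.")
  rownames(xy) <- ids
  xy
}

label_vector <- function(labels) {
  if (!is.data.frame(labels)) abort("`labels` must be a data frame.")
  if (!all(c("spot", "label") %in% names(labels))) {
    abort("`labels` must have columns spot, label.")
  }
  out <- setNames(as.character(labels$label), as.character(labels$spot))
  if (anyNA(out)) abort("missing label values.")
  out
}

#' Align embedding, coordinates and (optionally) labels to one spot order
#'
#' Restricts all tables to their common spots and reorders coordinates and
#' labels to the embedding's row order, which is canonical for every
#' downstream matrix. Spots present in only some of the inputs are dropped
#' with a message; an empty intersection is an error.
#'
#' @param embedding Embedding tibble.
#' @param coords Coordinates tibble (`spot`, `x`, `y`).
#' @param labels Optional labels tibble (`spot`, `label`).
#' @param verbose Report dropped-spot counts.
#' @return A list with elements `embedding`, `coords` and (if given)
#'   `labels`, all sharing identical spot order.
#' @examples
#' emb <- tibble::tibble(spot = c("a", "b", "c"), d1 = 1:3)
#' xy  <- tibble::tibble(spot = c("c", "b", "a", "z"), x = 1:4, y = 0)
#' align_spots(emb, xy)$coords$spot
#' @export
align_spots <- function(embedding, coords, labels = NULL, verbose = FALSE) {
  emb_ids <- as.character(embedding$spot)
  keep <- intersect(emb_ids, as.character(coords$spot))
  if (!is.null(labels)) keep <- intersect(keep, as.character(labels$spot))
  if (length(keep) == 0L) {
    abort("no spots shared between embedding and coordinates/labels.")
  }
  keep <- emb_ids[emb_ids %in% keep]  # embedding order wins
  n_drop <- length(emb_ids) - length(keep)
  if (n_drop > 0 || length(keep) < nrow(coords)) {
    log_msg(verbose, "alignment kept %d spots (dropped %d from embedding, %d from coordinates)",
            length(keep), n_drop, nrow(coords) - length(keep))
  }
  out <- list(
    embedding = embedding[match(keep, emb_ids), , drop = FALSE],
    coords = coords[match(keep, as.character(coords$spot)), , drop = FALSE]
  )
  if (!is.null(labels)) {
    out$labels <- labels[match(keep, as.character(labels$spot)), , drop = FALSE]
  }
  out
}
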