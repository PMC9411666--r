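# ggplot2 diagnostics for scores, rankings and spatial fields.

#' @describeIn score_embedding Bar chart of the per-dimension statistic with
#'   the filtered score marked.
#' @param object An `mpmim_score` / `mpmim_ranking` object (autoplot).
#' @param ... Unused.
#' @method autoplot mpmim_score
#' @export
autoplot.mpmim_score <- function(object, ...) {
  df <- object$dimensions[object$dimensions$defined, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dimension, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$score, linetype = "dashed") +
    ggplot2::labs(
      x = "embedding dimension",
      y = if (object$statistic == "moran") "Moran's I" else "1 - Geary's C",
      title = sprintf("%s: %s-filtered score %.3f", object$name,
                      object$filter_type, object$score)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn rank_embeddings Scores by rank, best embedding first.
#' @method autoplot mpmim_ranking
#' @export
autoplot.mpmim_ranking <- function(object, ...) {
  df <- object$ranking
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$name, .data$rank),
                                   y = .data$score)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$name, yend = min(df$score)),
                          linewidth = 0.3, colour = "grey60") +
    ggplot2::labs(
      x = NULL,
      y = sprintf("%s-filtered %s", object$config$filter_type,
                  if (object$config$statistic == "moran") "Moran's I"
                  else "1 - Geary's C"),
      title = "Embedding ranking (left = best)"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a per-spot field on the lattice
#'
#' Scatter of spot positions coloured by a value (an embedding dimension, a
#' label, a residual) — a quick visual check of spatial structure.
#'
#' @param coords Coordinates tibble.
#' @param values Vector of per-spot values in coordinate order, or the name
#'   of a column in `coords`.
#' @param point_size Marker size.
#' @return A ggplot object.
#' @export
plot_spot_field <- function(coords, values, point_size = 2) {
  if (is.character(values) && length(values) == 1L &&
      values %in% names(coords)) {
    values <- coords[[values]]
  }
  if (length(values) != nrow(coords)) {
    abort("`values` must supply one value per spot.")
  }
  df <- tibble(x = coords$x, y = coords$y, value = values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$value)) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "array x", y = "array y") +
    ggplot2::theme_minimal()
}
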