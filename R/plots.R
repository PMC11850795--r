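#' Plot cell tracks
#'
#' 2D track overlay, optionally coloured by a per-track label (e.g. the
#' behaviour cluster).
#'
#' @param cells a cell table with tracked rows.
#' @param colour_by optional column name to colour tracks by.
#' @return a ggplot object.
#' @export
plot_tracks <- function(cells, colour_by = NULL) {
  validate_cell_table(cells)
  tracked <- cells[is_tracked(cells), , drop = FALSE]
  tracked <- dplyr::arrange(tracked, .data$track_id, .data$frame)
  p <- ggplot2::ggplot(tracked,
                       ggplot2::aes(x = .data$x, y = .data$y, group = .data$track_id))
  p <- if (is.null(colour_by)) {
    p + ggplot2::geom_path(alpha = 0.6)
  } else {
    p + ggplot2::geom_path(ggplot2::aes(colour = factor(.data[[colour_by]])), alpha = 0.8) +
      ggplot2::labs(colour = colour_by)
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot cells coloured by region
#'
#' Scatter of cell centroids coloured by their niche/region assignment.
#'
#' @param cells a cell table.
#' @param regions a `region_assignment` from [kmeans_regions()] (or any
#'   tibble with `cell_id` and `region`).
#' @return a ggplot object.
#' @export
plot_regions <- function(cells, regions) {
  validate_cell_table(cells)
  joined <- dplyr::inner_join(cells, regions, by = "cell_id")
  ggplot2::ggplot(joined, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = factor(.data$region))) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "region") +
    ggplot2::theme_minimal()
}
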