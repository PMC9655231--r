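#' Plot a gridded count field
#'
#' Tile map of the per-cell counts; planted truth cells (if the grid came
#' from [generate_counts()]) are outlined.
#'
#' @param object A `grid_lattice` tibble with a `value` column.
#' @param ... Unused.
#' @export
autoplot.grid_lattice <- function(object, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$col, y = .data$row,
                                    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "count") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
  truth <- attr(object, "truth", exact = TRUE)
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_tile(
      data = tibble::as_tibble(object)[truth, ],
      fill = NA, colour = "white", linewidth = 0.3
    )
  }
  p
}

#' Plot a hotspot detection
#'
#' Count tile map with detected hotspot cells outlined in red.
#'
#' @param object A `hotspot_detection` tibble.
#' @param ... Unused.
#' @export
autoplot.hotspot_detection <- function(object, ...) {
  base <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(base, ggplot2::aes(x = .data$col, y = .data$row,
                                          fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "count") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = paste0("hotspots: ", attr(object, "method", exact = TRUE)),
      x = NULL, y = NULL
    )
  hot <- base[base$hotspot, ]
  if (nrow(hot)) {
    p <- p + ggplot2::geom_tile(data = hot, fill = NA, colour = "red",
                                linewidth = 0.4)
  }
  p
}

#' Plot benchmark results
#'
#' F1 (when truth-based indicators are present) or DCR per method across
#' replicates, as boxplots.
#'
#' @param object A `hotspot_benchmark` tibble.
#' @param ... Unused.
#' @export
autoplot.hotspot_benchmark <- function(object, ...) {
  yvar <- if ("f1" %in% names(object)) "f1" else "dcr"
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$method, y = .data[[yvar]])) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = yvar)
}
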