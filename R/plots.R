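# ggplot2 displays of saliency maps, spike rasters, and experiment
# summaries.

#' Plot a saliency map
#'
#' @param map A `saliency_map`.
#' @param display Optional `display_spec`; item centers are overlaid.
#' @return A ggplot object.
#' @export
plot_saliency <- function(map, display = NULL) {
  df <- tidyr::expand_grid(y = seq_len(nrow(map$values)),
                           x = seq_len(ncol(map$values)))
  df$s <- as.vector(t(map$values))[(df$y - 1) * ncol(map$values) + df$x]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$s)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "saliency", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
  if (!is.null(display)) {
    it <- display$items
    p <- p + ggplot2::annotate("text", x = it$x + 1, y = it$y + 1,
                               label = it$identity, color = "white",
                               size = 3)
  }
  p
}

#' Spike raster of a population
#'
#' @param population A `spike_population`.
#' @return A ggplot object.
#' @export
plot_raster <- function(population) {
  df <- dplyr::bind_rows(lapply(seq_along(population$trains), function(i) {
    tibble::tibble(neuron = i, t = population$trains[[i]])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$neuron)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (ms)", y = "neuron") +
    ggplot2::xlim(0, population$T) +
    ggplot2::theme_minimal()
}

#' Bar chart of median latencies by condition
#'
#' @param experiment A `load_experiment`.
#' @return A ggplot object.
#' @export
plot_latencies <- function(experiment) {
  df <- experiment$summaries
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = .data$median_latency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "median latency (ms)",
                  title = experiment$name) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Bar chart of distractor interference by cell
#'
#' Shows each interference score with its permutation noise floor.
#'
#' @param experiment A `load_experiment`.
#' @return A ggplot object.
#' @export
plot_interference <- function(experiment) {
  df <- experiment$interference
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$interference)) +
    ggplot2::geom_col(fill = "indianred") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$floor_lo,
                                        ymax = .data$floor_hi),
                           width = 0.3, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "interference (ms)",
                  title = paste(experiment$name,
                                "(dashed: zero-effect noise floor)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname plot_latencies
#' @param object A `load_experiment`.
#' @param ... Unused.
#' @export
autoplot.load_experiment <- function(object, ...) {
  plot_latencies(object)
}
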