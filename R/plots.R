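# ggplot2 views of the main result types.

#' Bar chart of the module census
#'
#' @param modules A `motif_modules` tibble.
#' @return A ggplot: module counts per topological pool.
#' @export
plot_module_census <- function(modules) {
  counts <- dplyr::count(tibble::as_tibble(modules), .data$topo_type)
  ggplot2::ggplot(counts, ggplot2::aes(x = stats::reorder(.data$topo_type,
                                                          -.data$n),
                                       y = .data$n)) +
    ggplot2::geom_col(fill = "#377EB8") +
    ggplot2::labs(x = "module type", y = "modules") +
    ggplot2::theme_minimal()
}

#' Heatmap of module-module connectivity z-scores
#'
#' @param sv Superview tibble from [superview()].
#' @param layer Single layer letter to display.
#' @return A ggplot tile map of z-scores for the chosen layer.
#' @export
plot_superview <- function(sv, layer) {
  rows <- sv[sv$layer == layer, , drop = FALSE]
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$module_a, y = .data$module_b,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B") +
    ggplot2::labs(title = paste("Layer", layer), x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Boxplots of stability scores by sampling fraction
#'
#' @param object A `stability_result` from [stability_analysis()].
#' @param ... Unused.
#' @return A ggplot: per-repetition mean best-match score against sampling
#'   fraction, one panel per metric.
#' @exportS3Method ggplot2::autoplot
autoplot.stability_result <- function(object, ...) {
  means <- glance.stability_result(object)
  ggplot2::ggplot(means, ggplot2::aes(x = factor(.data$fraction),
                                      y = .data$mean_best_score)) +
    ggplot2::geom_boxplot(fill = "#4DAF4A", alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric)) +
    ggplot2::labs(x = "fraction of edges kept", y = "mean best-match score") +
    ggplot2::theme_minimal()
}

#' Activity-score profile across contrasts
#'
#' @param object A `module_activity` tibble.
#' @param ... Unused.
#' @return A ggplot: `s_a` per module and contrast.
#' @exportS3Method ggplot2::autoplot
autoplot.module_activity <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$contrast, y = .data$s_a,
                               group = .data$module)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "module activity s_a") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
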