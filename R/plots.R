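#' Plot component stability and variance explained
#'
#' @param object A `consensus_ica` object.
#' @param X Optional data matrix; adds a variance-explained panel value.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.consensus_ica <- function(object, X = NULL, ...) {
  df <- tidy(object, X = X)
  df <- tidyr::pivot_longer(df, -"component",
                            names_to = "metric", values_to = "value")
  df$component <- factor(df$component, levels = names(object$stability))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Consensus ICA component summary") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of component weights across samples
#'
#' @param dec A `consensus_ica` object.
#' @param ann Optional [sample_annotation()]; the first factor column orders
#'   the samples.
#' @return A ggplot.
#' @export
plot_weights <- function(dec, ann = NULL) {
  df <- augment(dec, ann = ann)
  if (!is.null(ann) && ncol(ann$factors)) {
    fac <- colnames(ann$factors)[1L]
    df$sample <- factor(df$sample, levels = unique(df$sample[order(df[[fac]])]))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$component,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "sample", y = NULL, title = "Component weights (M)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Source-signal distribution of one component
#'
#' Highlights the |z| threshold used for top-feature extraction: consensus
#' ICA components typically show a near-zero bulk with a few strong
#' contributors in one or both tails.
#'
#' @param dec A `consensus_ica` object.
#' @param component Component index or name.
#' @param z_threshold Cutoff drawn as vertical lines. Default 3.
#' @return A ggplot.
#' @export
plot_component_signal <- function(dec, component, z_threshold = 3) {
  j <- resolve_component(dec, component)
  s <- dec$S[, j]
  z <- (s - mean(s)) / stats::sd(s)
  df <- tibble::tibble(z = z)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey40") +
    ggplot2::geom_vline(xintercept = c(-z_threshold, z_threshold),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(title = paste0(colnames(dec$S)[j], " source signal"),
                  x = "z-scored contribution", y = "features") +
    ggplot2::theme_minimal()
}
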