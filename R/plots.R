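#' Plotting helpers
#'
#' ggplot2-based quick looks: map slices, training curves, and the
#' correlation-versus-solvent-content diagnostic.
#'
#' @name plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of one section of a map
#'
#' @param object a `map_grid`.
#' @param section z-section index (default: middle).
#' @param ... unused.
#' @return a ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.map_grid <- function(object, section = NULL, ...) {
  n <- dim(object$values)
  if (is.null(section)) section <- (n[3] + 1) %/% 2
  df <- expand.grid(x = seq_len(n[1]), y = seq_len(n[2]))
  df$value <- as.vector(object$values[, , section])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s map, section z = %d", object$flavor,
                                  section),
                  x = "grid x", y = "grid y", fill = "value") +
    ggplot2::theme_minimal()
}

#' Training-loss curve of a fitted model
#'
#' @param object an `xtal_model`.
#' @param ... unused.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.xtal_model <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$step,
                                               y = .data$loss)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "optimizer step", y = "composite loss") +
    ggplot2::theme_minimal()
}

#' Map correlation versus solvent content
#'
#' Scatter of per-example in-model-region Pearson correlations against the
#' solvent fraction of the ground-truth cell; used to check whether empty
#' space in the cell drives completion difficulty.
#'
#' @param df tibble with columns `solvent` and `cc`.
#' @return a ggplot.
#' @export
plot_cc_vs_solvent <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$solvent, y = .data$cc)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "solvent fraction", y = "model-region Pearson CC") +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
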