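#' Plot the connectivity metric time series of an experiment
#'
#' @param object A `cr_experiment`.
#' @param ... Unused.
#' @return A ggplot: average signed weight and its excitatory /
#'   inhibitory components over time, with the stimulation period shaded.
#' @method autoplot cr_experiment
#' @export
autoplot.cr_experiment <- function(object, ...) {
  cfg <- object$config
  t_on <- cfg$periods[["stim_on"]] * 1000
  long <- tidyr::pivot_longer(object$metrics,
                              cols = c("c_av", "c_ee", "c_ii"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$time_ms / 1000, y = .data$value,
                               colour = .data$metric)) +
    ggplot2::annotate("rect", xmin = 0, xmax = t_on / 1000,
                      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "red") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("%s, K = %g, sample %d",
                                  cfg$protocol, cfg$K, cfg$sample_id)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Raster plot of a spike record
#'
#' @param raster Spike raster tibble (`neuron`, `time_ms`).
#' @param window Optional length-2 time window, ms.
#' @return A ggplot.
#' @export
plot_raster <- function(raster, window = NULL) {
  if (!is.null(window))
    raster <- raster[raster$time_ms >= window[1] &
                       raster$time_ms < window[2], ]
  ggplot2::ggplot(raster, ggplot2::aes(x = .data$time_ms,
                                       y = .data$neuron)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "neuron") +
    ggplot2::theme_minimal()
}

#' Heatmap of a signed (or sorted) connectivity matrix
#'
#' @param mat Signed matrix, e.g. from [signed_weights()] or
#'   [sort_connectivity()].
#' @param title Plot title.
#' @return A ggplot with a diverging palette (inhibitory negative in
#'   blue, excitatory positive in red).
#' @export
plot_connectivity <- function(mat, title = "connectivity") {
  df <- tibble::tibble(
    post = rep(seq_len(nrow(mat)), ncol(mat)),
    pre = rep(seq_len(ncol(mat)), each = nrow(mat)),
    w = as.vector(mat))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pre, y = .data$post,
                                   fill = .data$w)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-1, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "pre", y = "post", fill = "weight", title = title) +
    ggplot2::theme_minimal()
}

#' Resetting-index curve
#'
#' @param ri Tibble from [resetting_index()], optionally with a
#'   `protocol` column for grouping.
#' @return A ggplot of `E` against the lag from stimulus onset.
#' @export
plot_resetting_index <- function(ri) {
  aes <- if ("protocol" %in% names(ri))
    ggplot2::aes(x = .data$delta_t, y = .data$E,
                 colour = .data$protocol)
  else ggplot2::aes(x = .data$delta_t, y = .data$E)
  ggplot2::ggplot(ri, aes) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "lag from onset (ms)", y = "resetting index E") +
    ggplot2::theme_minimal()
}

#' Across-sample boxplots of a batch metric
#'
#' @param summary Batch summary tibble from [run_batch()].
#' @param metric Summary column to plot.
#' @return A ggplot of per-protocol boxplots across samples.
#' @export
plot_metric_box <- function(summary, metric = "c_av_on") {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$protocol,
                               y = .data[[metric]])) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}
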