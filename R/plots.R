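#' Heat-map view of an experiment grid
#'
#' Mean test accuracy per (capacity level, training-set size) cell, one panel
#' per architecture family.
#'
#' @param object A `grid_result` from [run_experiment()].
#' @param metric `"test"` or `"train"` accuracy.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grid_result <- function(object, metric = c("test", "train"), ...) {
  metric <- match.arg(metric)
  col <- paste0("mean_", metric)
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$N), y = factor(.data$level),
    fill = .data[[col]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data[[col]])),
                       size = 3) +
    ggplot2::facet_wrap(~family) +
    ggplot2::scale_fill_gradient(low = "white",
                                 high = if (metric == "test") "#2166ac" else "#b2182b",
                                 limits = c(0.5, 1)) +
    ggplot2::labs(x = "training examples N", y = "capacity level log10(C)",
                  fill = paste("mean", metric, "accuracy"))
}

#' Cross-over plot of train and test accuracy against N
#'
#' @param curve A tibble from [crossover_curve()].
#' @return A ggplot object with both accuracy curves on a log-scaled N axis.
#' @export
plot_crossover <- function(curve) {
  df <- tidyr::pivot_longer(curve, c("mean_train", "mean_test"),
                            names_to = "split", values_to = "accuracy",
                            names_prefix = "mean_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$N, y = .data$accuracy,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::geom_hline(yintercept = c(0.8, 1), linetype = "dotted") +
    ggplot2::labs(x = "training examples N", y = "accuracy", colour = NULL)
}

#' Probe-score dot plot
#'
#' Positivity scores of each trained model on the diagnostic probes, with the
#' classification threshold marked.
#'
#' @param scores A tibble from [probe_scores()].
#' @return A ggplot object.
#' @export
plot_probe_scores <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$probe, y = .data$score)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = scores$theta[1], colour = "red",
                        linetype = "dotted") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "positivity score")
}
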