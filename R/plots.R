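#' Plot a confusion matrix
#'
#' Heatmap of the confusion counts of a [evaluate_predictions()] result.
#'
#' @param object A `ttp_evaluation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ttp_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$confusion,
                  ggplot2::aes(x = .data$truth, y = .data$pred,
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "true class", y = "predicted class", fill = "count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 5),
                   axis.text.y = ggplot2::element_text(size = 5))
}

#' Misclassification error against truncation percentage
#'
#' @param result An `experiment_result`.
#' @param ... Unused.
#' @return A ggplot of the per-percent mean error with per-class points.
#' @export
autoplot.experiment_result <- function(result, ...) {
  per <- result$per_class
  means <- dplyr::summarise(dplyr::group_by(per, .data$percent),
                            m = mean(.data$m), .groups = "drop")
  ggplot2::ggplot(per, ggplot2::aes(x = .data$percent, y = .data$m)) +
    ggplot2::geom_jitter(width = 0.4, height = 0, alpha = 0.25, size = 0.6) +
    ggplot2::geom_line(data = means, colour = "firebrick", linewidth = 1) +
    ggplot2::geom_point(data = means, colour = "firebrick", size = 2) +
    ggplot2::labs(x = "truncation (%)", y = "misclassification error") +
    ggplot2::theme_minimal()
}

#' Unique-TTP saturation plot
#'
#' @param saturation Tibble from [ttp_saturation()] (optionally row-bound for
#'   several solids with a `name` column).
#' @return A ggplot of unique TTP count against orientations sampled.
#' @export
plot_saturation <- function(saturation) {
  aes <- if ("name" %in% names(saturation))
    ggplot2::aes(x = .data$n, y = .data$unique_ttps, group = .data$name)
  else ggplot2::aes(x = .data$n, y = .data$unique_ttps)
  ggplot2::ggplot(saturation, aes) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "orientations sampled",
                  y = "unique truncated profiles") +
    ggplot2::theme_minimal()
}
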