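#' Plot an evaluation report
#'
#' Scatter of condition-level estimated vs measured metabolic power, one
#' point per (subject, condition), with the identity line.
#'
#' @param object An `ee_report` from [run_use_case()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ee_report
#' @export
autoplot.ee_report <- function(object, ...) {
  ggplot2::ggplot(object$cond_estimates,
                  ggplot2::aes(x = .data$truth, y = .data$estimate,
                               colour = .data$subject_id)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(
      x = "Measured energy expenditure (W)",
      y = "Estimated energy expenditure (W)",
      colour = "Subject",
      title = sprintf("%s / %s: %.1f%% mean error",
                      object$use_case, object$model,
                      object$mean_percent_error)) +
    ggplot2::theme_minimal()
}

#' Plot a condition-ordering confusion matrix
#'
#' Heat map of the ordering confusion matrix: conditions ranked by measured
#' power on the vertical axis (increasing), by estimated power on the
#' horizontal; a value of 1 on the diagonal is a perfect match across all
#' subjects.
#'
#' @param confusion A `K x K` matrix from [ordering_confusion()], or an
#'   `ee_report` carrying one.
#' @return A ggplot object.
#' @export
plot_ordering_confusion <- function(confusion) {
  if (inherits(confusion, "ee_report")) confusion <- confusion$confusion
  if (is.null(confusion)) abort("Report has no confusion matrix")
  df <- tidyr::expand_grid(true_rank = seq_len(nrow(confusion)),
                           est_rank = seq_len(ncol(confusion)))
  df$value <- confusion[cbind(df$true_rank, df$est_rank)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$est_rank, y = .data$true_rank,
                                   fill = .data$value)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue4",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "Estimated rank", y = "Measured rank",
                  fill = "Fraction\nof subjects") +
    ggplot2::theme_minimal()
}
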