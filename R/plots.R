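#' Plot an evaluation report
#'
#' @param object A `vw_eval`.
#' @param which `"roc"`, `"pr"` or `"bins"` (precision by probability bin).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vw_eval <- function(object, which = c("roc", "pr", "bins"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_path() +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::geom_vline(xintercept = object$achieved_fpr,
                          linetype = "dotted", colour = "firebrick") +
      ggplot2::labs(
        title = sprintf("ROC (AUC = %.3f)", object$auc),
        subtitle = sprintf("threshold mu = %.3f at FPR = %.3f",
                           object$threshold, object$achieved_fpr),
        x = "False positive rate", y = "True positive rate") +
      ggplot2::coord_equal() +
      ggplot2::theme_minimal()
  } else if (which == "pr") {
    ggplot2::ggplot(object$pr, ggplot2::aes(x = .data$recall,
                                            y = .data$precision)) +
      ggplot2::geom_path() +
      ggplot2::geom_hline(yintercept = object$n_pos / object$n,
                          linetype = "dashed", colour = "grey60") +
      ggplot2::labs(title = "Precision-recall",
                    x = "Recall", y = "Precision") +
      ggplot2::ylim(0, 1) +
      ggplot2::theme_minimal()
  } else {
    bins <- object$bins %>%
      mutate(bin = sprintf("[%.2f, %.2f%s", .data$bin_lo, .data$bin_hi,
                           ifelse(.data$bin_hi == 1, "]", ")")))
    ggplot2::ggplot(bins, ggplot2::aes(x = stats::reorder(.data$bin, .data$bin_lo),
                                       y = .data$precision)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4,
                         size = 3) +
      ggplot2::labs(title = "Precision by prediction-probability bin",
                    subtitle = "bin sample counts above bars",
                    x = "Probability bin", y = "Precision") +
      ggplot2::ylim(0, 1.05) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
  }
}

#' Plot aggregated feature importance
#'
#' @param model A `vw_model`.
#' @param top_n Show the `top_n` most important base features.
#' @return A ggplot.
#' @export
plot_importance <- function(model, top_n = 20) {
  imp <- aggregate_importance(feature_importance(model), model$manifest) %>%
    head(top_n)
  ggplot2::ggplot(imp, ggplot2::aes(
    x = stats::reorder(.data$feature_id, .data$importance),
    y = .data$importance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(title = "Feature importance (sum of squared split gains)",
                  x = NULL, y = "Normalized importance") +
    ggplot2::theme_minimal()
}
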