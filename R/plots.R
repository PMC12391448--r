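# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Loss curves of a training run
#'
#' @param object A `trained_head`.
#' @param ... Unused.
#' @return A ggplot of train and validation loss against epoch.
#' @export
autoplot.trained_head <- function(object, ...) {
  df <- object$curves |>
    tidyr::pivot_longer(c("train_loss", "val_loss"),
                        names_to = "split", values_to = "loss") |>
    dplyr::mutate(split = sub("_loss$", "", .data$split))
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean loss", colour = NULL,
                  title = paste(object$config$head_kind, "head")) +
    ggplot2::theme_minimal()
}

#' ROC curve of an evaluation report
#'
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot of the ROC curve with the AUC in the title.
#' @export
autoplot.metrics_report <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", object$summary$auc)) +
    ggplot2::theme_minimal()
}

#' Per-head loss and gap summary of a comparison
#'
#' @param object A `head_comparison`.
#' @param ... Unused.
#' @return A ggplot of final losses and overfitting gap per head and seed.
#' @export
autoplot.head_comparison <- function(object, ...) {
  df <- object$results |>
    tidyr::pivot_longer(c("train_loss", "val_loss", "overfit_gap"),
                        names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$head_kind, .data$value)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
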