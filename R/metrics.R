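# Binary-classification evaluation: confusion counts, sensitivity/
# specificity/balanced accuracy, and ROC/AUC by full threshold sweep with
# trapezoid integration (equal, with ties counted 1/2, to the normalized
# Mann-Whitney U statistic).

#' Confusion counts
#'
#' @param labels 0/1 truth vector.
#' @param predictions 0/1 predicted classes, same length.
#' @return One-row tibble with `tp`, `tn`, `fp`, `fn` (they partition the
#'   sample).
#' @examples
#' confusion_counts(c(1, 0, 1, 0), c(1, 1, 0, 0))
#' @export
confusion_counts <- function(labels, predictions) {
  labels <- as.numeric(labels); predictions <- as.numeric(predictions)
  if (length(labels) != length(predictions)) {
    stop("labels and predictions must have equal length", call. = FALSE)
  }
  if (any(!labels %in% c(0, 1)) || any(!predictions %in% c(0, 1))) {
    stop("labels and predictions must be binary 0/1", call. = FALSE)
  }
  tibble::tibble(
    tp = sum(labels == 1 & predictions == 1),
    tn = sum(labels == 0 & predictions == 0),
    fp = sum(labels == 0 & predictions == 1),
    fn = sum(labels == 1 & predictions == 0)
  )
}

#' Sensitivity, specificity and balanced accuracy from counts
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `bacc = (sensitivity + specificity) / 2`.
#'
#' @param tp,tn,fp,fn Nonnegative counts; both `tp + fn` and `tn + fp`
#'   must be positive (each class must appear in the truth).
#' @return One-row tibble with `sensitivity`, `specificity`, `bacc`.
#' @examples
#' classification_metrics(90, 80, 20, 10)
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  if (is.data.frame(tp)) {
    cc <- tp; tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  }
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  if (tp + fn == 0) {
    stop("sensitivity undefined: no positive samples (TP + FN = 0)",
         call. = FALSE)
  }
  if (tn + fp == 0) {
    stop("specificity undefined: no negative samples (TN + FP = 0)",
         call. = FALSE)
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble::tibble(sensitivity = sens, specificity = spec,
                 bacc = (sens + spec) / 2)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every distinct score as a threshold, yielding a monotone curve
#' from (0, 0) to (1, 1); the AUC is the trapezoid integral, which equals
#' the Mann-Whitney probability that a random positive outscores a random
#' negative (ties counted 1/2).
#'
#' @param labels 0/1 truth vector; both classes must be present.
#' @param scores Finite numeric scores, higher meaning more positive.
#' @return List with `roc` (tibble of `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.numeric(labels); scores <- as.numeric(scores)
  stopifnot(length(labels) == length(scores))
  if (any(!labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # collapse tied scores into single thresholds
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  cum_tp <- unname(cumsum(tp_g))
  cum_fp <- unname(cumsum(n_g - tp_g))
  roc <- tibble::tibble(
    threshold = c(Inf, s[!duplicated(s)]),
    fpr = c(0, cum_fp / N),
    tpr = c(0, cum_tp / P)
  )
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Full evaluation report for binary scores
#'
#' Thresholds the class-1 probability at `threshold` for the confusion
#' counts and derived metrics, and sweeps it for ROC/AUC.
#'
#' @param labels 0/1 truth vector.
#' @param scores Class-1 probabilities (or any monotone score for the ROC;
#'   the threshold applies to these values directly).
#' @param threshold Decision cut on `scores` (default 0.5).
#' @return A `metrics_report`: list with `counts` (tp/tn/fp/fn tibble),
#'   `summary` (sensitivity, specificity, bacc, auc), and `roc`.
#' @export
metrics_report <- function(labels, scores, threshold = 0.5) {
  cc <- confusion_counts(labels, as.numeric(scores >= threshold))
  cm <- classification_metrics(cc)
  ra <- roc_auc(labels, scores)
  structure(list(counts = cc,
                 summary = dplyr::bind_cols(cm,
                                            tibble::tibble(auc = ra$auc)),
                 roc = ra$roc,
                 threshold = threshold),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<metrics_report> BACC %.3f  SEN %.3f  SPE %.3f  ",
                     "AUC %.3f (threshold %.2f)\n"),
              s$bacc, s$sensitivity, s$specificity, s$auc, x$threshold))
  cat("  counts:", sprintf("TP=%d TN=%d FP=%d FN=%d", x$counts$tp,
                           x$counts$tn, x$counts$fp, x$counts$fn), "\n")
  invisible(x)
}

#' @rdname metrics_report
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @export
glance.metrics_report <- function(x, ...) {
  dplyr::bind_cols(x$counts, x$summary)
}

#' Evaluate a trained head on labelled data
#'
#' @param model A `trained_head`.
#' @param data Data frame of features plus a `label` column.
#' @param shots Optional shot count for Monte-Carlo readout.
#' @param seed Seed for shot sampling.
#' @param threshold Decision threshold on the class-1 probability.
#' @return A [metrics_report()].
#' @export
evaluate_head <- function(model, data, shots = NULL, seed = NULL,
                          threshold = 0.5) {
  stopifnot(inherits(model, "trained_head"))
  preds <- stats::predict(model, data, shots = shots, seed = seed)
  metrics_report(data$label, preds$.pred_prob, threshold = threshold)
}
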