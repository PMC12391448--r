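# The VQC-vs-FC comparison experiment: identical data and training
# schedule, heads differing only in the middle block. Reports final
# train/validation losses, the overfitting gap, BACC/AUC, and the
# middle-block trainable parameter counts, across seeds.

#' Compare the VQC and FC heads on one synthetic dataset
#'
#' Generates the dataset once from `spec`, then trains every head kind with
#' every seed under the same schedule and evaluates on the validation
#' split. The overfitting-gap comparison is a protocol, not a guaranteed
#' inequality: the report states the measured gaps.
#'
#' @param spec A [synthetic_spec()].
#' @param head_kinds Character vector, subset of `c("vqc", "fc")`.
#' @param training A [train_config()]; its `seed` field is replaced by each
#'   entry of `seeds` in turn.
#' @param seeds Integer vector of training seeds.
#' @param n_qubits,n_layers Middle-block geometry shared by both heads.
#' @return A `head_comparison`: list with `results` (one tibble row per
#'   head x seed), `summary` (across-seed mean and sd per head), and the
#'   generating spec.
#' @export
compare_heads <- function(spec, head_kinds = c("vqc", "fc"),
                          training = train_config(), seeds = 0:2,
                          n_qubits = spec$n_features, n_layers = 2L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  head_kinds <- match.arg(head_kinds, c("vqc", "fc"), several.ok = TRUE)
  splits <- generate_splits(spec)
  rows <- list()
  for (kind in head_kinds) {
    cfg <- head_config(spec$n_features, n_qubits = n_qubits,
                       n_layers = n_layers, head_kind = kind)
    mid <- middle_block_params(n_qubits, n_layers)
    for (sd in seeds) {
      tc <- training
      tc$seed <- as.integer(sd)
      fit <- train_head(splits$train, cfg, tc, val_data = splits$val)
      rep <- evaluate_head(fit, splits$val)
      last <- fit$curves[nrow(fit$curves), ]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        head_kind = kind, seed = as.integer(sd),
        train_loss = last$train_loss, val_loss = last$val_loss,
        overfit_gap = last$val_loss - last$train_loss,
        bacc = rep$summary$bacc, auc = rep$summary$auc,
        middle_params = if (kind == "vqc") mid$vqc_params else
          mid$fc_weights + mid$fc_bias,
        middle_weights = if (kind == "vqc") mid$vqc_params else
          mid$fc_weights
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(.data$head_kind) |>
    dplyr::summarise(dplyr::across(
      c("train_loss", "val_loss", "overfit_gap", "bacc", "auc"),
      list(mean = mean, sd = stats::sd)),
      middle_params = .data$middle_params[1], .groups = "drop")
  structure(list(results = results, summary = summary, spec = spec,
                 n_qubits = n_qubits, n_layers = n_layers),
            class = "head_comparison")
}

#' @export
print.head_comparison <- function(x, ...) {
  cat("<head_comparison> ", nrow(x$results), " runs on ",
      x$spec$noise_kind, " data (N = ", x$n_qubits, ", K = ", x$n_layers,
      ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' @param comparison A `head_comparison` from [compare_heads()].
#' @param path Optional output path.
#' @return JSON text (invisibly when writing).
#' @export
comparison_to_json <- function(comparison, path = NULL) {
  stopifnot(inherits(comparison, "head_comparison"))
  obj <- list(spec = unclass(comparison$spec),
              n_qubits = comparison$n_qubits,
              n_layers = comparison$n_layers,
              results = comparison$results,
              summary = comparison$summary)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                          dataframe = "rows")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
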