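# Joint training of the hybrid head: SGD with momentum, two learning-rate
# groups (classical linear maps vs quantum rotation angles), cosine
# annealing to zero, weight decay on the classical group only, label
# smoothing, and a class-balanced resampling loader.

#' Configure the training protocol
#'
#' Defaults follow the reference protocol: 80 epochs of SGD with momentum
#' 0.9 and weight decay 1e-4, cosine annealing, learning rate 0.0004 for
#' the classical parameters and 10x that (0.004) for the VQC angles — the
#' circuit's bounded `[-1, 1]` output benefits from the larger step — and a
#' balanced resampling loader for imbalanced labels.
#'
#' @param epochs Training epochs.
#' @param lr_classical Learning rate for all linear maps.
#' @param lr_quantum Learning rate for the VQC rotation angles.
#' @param momentum SGD momentum.
#' @param weight_decay L2 decay, applied to classical parameters only
#'   (rotation angles are periodic; shrinking them toward 0 has no meaning).
#' @param label_smoothing Cross-entropy smoothing in `[0, 1)`.
#' @param schedule `"cosine"` (anneal to 0, no restarts) or `"constant"`.
#' @param balanced_resampling Draw each epoch's samples with equal expected
#'   class frequencies (oversampling the minority with replacement).
#' @param seed Seed controlling initialization, the loader and every other
#'   random draw; identical configs and seeds reproduce bit-identical runs
#'   in analytic mode.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 80L, lr_classical = 4e-4,
                         lr_quantum = 4e-3, momentum = 0.9,
                         weight_decay = 1e-4, label_smoothing = 0.1,
                         schedule = c("cosine", "constant"),
                         balanced_resampling = TRUE, seed = 0L) {
  schedule <- match.arg(schedule)
  stopifnot(epochs >= 1L, lr_classical >= 0, lr_quantum >= 0,
            momentum >= 0, momentum < 1, weight_decay >= 0,
            label_smoothing >= 0, label_smoothing < 1)
  structure(list(epochs = as.integer(epochs), lr_classical = lr_classical,
                 lr_quantum = lr_quantum, momentum = momentum,
                 weight_decay = weight_decay,
                 label_smoothing = label_smoothing, schedule = schedule,
                 balanced_resampling = isTRUE(balanced_resampling),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `lr0 * (1 + cos(pi * epoch / epochs)) / 2` for 0-based `epoch`; halfway
#' through training the rate is exactly `lr0 / 2`, and it anneals to 0.
#'
#' @param epoch 0-based epoch index.
#' @param epochs Total epochs.
#' @param lr0 Initial learning rate.
#' @return The scheduled learning rate.
#' @export
cosine_lr <- function(epoch, epochs, lr0) {
  lr0 * (1 + cos(pi * epoch / epochs)) / 2
}

#' Class-balanced epoch sample sequence
#'
#' Draws `n_draws` indices so each class is picked with probability 1/2 and
#' a member is then drawn uniformly within the class (oversampling with
#' replacement). Deterministic when `seed` is supplied; otherwise the draw
#' uses, and advances, the caller's RNG stream.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param n_draws Number of indices to emit (defaults to `length(labels)`).
#' @param seed Optional seed.
#' @return Integer vector of indices into `labels`.
#' @export
balanced_sample_indices <- function(labels, n_draws = length(labels),
                                    seed = NULL) {
  labels <- as.integer(labels)
  i0 <- which(labels == 0L); i1 <- which(labels == 1L)
  if (!length(i0) || !length(i1)) {
    stop("balanced resampling needs both classes present", call. = FALSE)
  }
  draw <- function() {
    cls <- stats::runif(n_draws) < 0.5
    out <- integer(n_draws)
    out[cls] <- i1[sample.int(length(i1), sum(cls), replace = TRUE)]
    out[!cls] <- i0[sample.int(length(i0), sum(!cls), replace = TRUE)]
    out
  }
  if (is.null(seed)) draw() else with_seed_local(seed, draw())
}

# map over matching weight/gradient/velocity structures
sgd_update <- function(weights, grads, vel, cfg, lr_c, lr_q) {
  upd <- function(p, g, v, lr, wd) {
    v_new <- cfg$momentum * v + g + wd * p
    list(p = p - lr * v_new, v = v_new)
  }
  for (nm in names(weights)) {
    if (nm == "vqc") {
      u <- upd(weights$vqc$angles, grads$vqc, vel$vqc, lr_q, 0)
      weights$vqc$angles <- u$p
      vel$vqc <- u$v
    } else {
      u <- upd(weights[[nm]], grads[[nm]], vel[[nm]], lr_c, cfg$weight_decay)
      weights[[nm]] <- u$p
      vel[[nm]] <- u$v
    }
  }
  list(weights = weights, vel = vel)
}

zero_like_weights <- function(weights) {
  lapply(weights, function(p) {
    if (inherits(p, "vqc_params")) array(0, dim(p$angles)) else p * 0
  })
}

#' Train a classification head
#'
#' Runs the joint protocol on a feature table: per-sample SGD with momentum,
#' the classical/quantum learning-rate split, cosine annealing, weight decay
#' on the classical group, label smoothing, and (optionally) the balanced
#' loader. Training always uses exact analytic expectations; shots are an
#' inference-time option. Per-epoch mean training loss (over the samples as
#' drawn) and validation loss (plain loader) are recorded.
#'
#' @param data Training data frame: numeric feature columns plus a 0/1
#'   `label` column.
#' @param config A [head_config()]; `in_dim` must match the feature count.
#' @param training A [train_config()].
#' @param val_data Validation data frame with the same columns (disjoint
#'   from `data`).
#' @return A `trained_head` object: `weights`, the configs, and `curves`, a
#'   tibble with `epoch`, `train_loss`, `val_loss`, `lr_classical`,
#'   `lr_quantum`.
#' @export
train_head <- function(data, config, training = train_config(),
                       val_data = NULL) {
  stopifnot(inherits(config, "head_config"), inherits(training, "train_config"))
  tr <- split_features_labels(data)
  if (ncol(tr$x) != config$in_dim) {
    stop("config$in_dim = ", config$in_dim, " but data has ", ncol(tr$x),
         " feature columns", call. = FALSE)
  }
  va <- if (!is.null(val_data)) split_features_labels(val_data)
  n_tr <- nrow(tr$x)

  set.seed(training$seed)
  weights <- init_head_weights(config)
  vel <- zero_like_weights(weights)
  curves <- vector("list", training$epochs)

  for (e in seq_len(training$epochs)) {
    fac <- if (training$schedule == "cosine") {
      (1 + cos(pi * (e - 1) / training$epochs)) / 2
    } else 1
    lr_c <- training$lr_classical * fac
    lr_q <- training$lr_quantum * fac
    idx <- if (training$balanced_resampling) {
      balanced_sample_indices(tr$y, n_tr)
    } else {
      sample.int(n_tr)
    }
    ep_loss <- numeric(length(idx))
    for (s in seq_along(idx)) {
      i <- idx[s]
      hg <- head_grad(config, weights, tr$x[i, ], tr$y[i],
                      training$label_smoothing)
      if (!is.finite(hg$loss)) {
        stop("training aborted: non-finite loss at epoch ", e,
             ", step ", s, call. = FALSE)
      }
      ep_loss[s] <- hg$loss
      u <- sgd_update(weights, hg$grads, vel, training, lr_c, lr_q)
      weights <- u$weights
      vel <- u$vel
    }
    val_loss <- if (!is.null(va)) {
      mean(vapply(seq_len(nrow(va$x)), function(i) {
        head_loss(head_forward(config, weights, va$x[i, ], shots = 0)$logits,
                  va$y[i], training$label_smoothing)
      }, numeric(1)))
    } else NA_real_
    curves[[e]] <- tibble::tibble(
      epoch = e, train_loss = mean(ep_loss), val_loss = val_loss,
      lr_classical = lr_c, lr_quantum = lr_q)
  }

  structure(list(config = config, training = training, weights = weights,
                 curves = dplyr::bind_rows(curves),
                 feature_names = colnames(tr$x)),
            class = "trained_head")
}

#' @export
print.trained_head <- function(x, ...) {
  cat("<trained_head> ", x$config$head_kind, " head, ",
      x$training$epochs, " epochs\n", sep = "")
  last <- x$curves[nrow(x$curves), ]
  cat(sprintf("  final train loss %.4f, val loss %s\n", last$train_loss,
              ifelse(is.na(last$val_loss), "NA",
                     sprintf("%.4f", last$val_loss))))
  invisible(x)
}

#' Predict with a trained head
#'
#' @param object A `trained_head`.
#' @param new_data Data frame of feature columns (a `label` column, if
#'   present, is ignored).
#' @param shots Optional shot count for Monte-Carlo readout (default: the
#'   analytic expectations used in training).
#' @param seed Seed for shot sampling.
#' @param ... Unused.
#' @return A tibble with `.pred_prob` (softmax probability of class 1),
#'   `.pred_class` (threshold 0.5), and the two logits.
#' @export
predict.trained_head <- function(object, new_data, shots = NULL,
                                 seed = NULL, ...) {
  x <- new_data[setdiff(names(new_data), "label")]
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  rows <- lapply(seq_len(nrow(x)), function(i) {
    fw <- head_forward(object$config, object$weights, x[i, ],
                       shots = shots,
                       seed = if (is.null(seed)) NULL else seed + i)
    tibble::tibble(.pred_prob = fw$prob,
                   .pred_class = as.integer(fw$prob >= 0.5),
                   logit_0 = fw$logits[1], logit_1 = fw$logits[2])
  })
  dplyr::bind_rows(rows)
}

#' Overfitting gap of a training run
#'
#' The gap is validation loss minus training loss; the scalar value is the
#' gap at the final epoch and `series` carries the per-epoch gap.
#'
#' @param x A `trained_head` or a data frame with `train_loss` and
#'   `val_loss` columns (and optionally `epoch`).
#' @return List with `gap` (final-epoch scalar) and `series` (tibble of
#'   `epoch`, `gap`).
#' @export
overfit_gap <- function(x) {
  curves <- if (inherits(x, "trained_head")) x$curves else x
  stopifnot(is.data.frame(curves),
            all(c("train_loss", "val_loss") %in% names(curves)))
  gap <- curves$val_loss - curves$train_loss
  epoch <- if ("epoch" %in% names(curves)) curves$epoch else
    seq_along(gap)
  list(gap = gap[length(gap)],
       series = tibble::tibble(epoch = epoch, gap = gap))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training curves of a fitted head
#'
#' @param x A `trained_head`.
#' @param ... Unused.
#' @return The curves tibble (`epoch`, `train_loss`, `val_loss`,
#'   `lr_classical`, `lr_quantum`).
#' @export
tidy.trained_head <- function(x, ...) x$curves

#' One-row summary of a fitted head
#'
#' @param x A `trained_head`.
#' @param ... Unused.
#' @return Tibble with head kind, epochs, final losses, overfitting gap and
#'   middle-block parameter count.
#' @export
glance.trained_head <- function(x, ...) {
  last <- x$curves[nrow(x$curves), ]
  n <- x$config$n_qubits
  tibble::tibble(
    head_kind = x$config$head_kind,
    epochs = x$training$epochs,
    train_loss = last$train_loss,
    val_loss = last$val_loss,
    overfit_gap = last$val_loss - last$train_loss,
    middle_params = if (x$config$head_kind == "vqc")
      count_params(n, x$config$n_layers) else n^2 + n
  )
}

# --- model serialization ---------------------------------------------------

#' Save a trained head to JSON
#'
#' @param model A `trained_head`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_head <- function(model, path) {
  stopifnot(inherits(model, "trained_head"))
  w <- model$weights
  obj <- list(
    config = unclass(model$config),
    training = unclass(model$training),
    feature_names = model$feature_names,
    curves = model$curves,
    weights = list(
      W_in = w$W_in, b_in = w$b_in, W_out = w$W_out, b_out = w$b_out,
      W_mid = w$W_mid, b_mid = w$b_mid,
      vqc = if (!is.null(w$vqc)) jsonlite::fromJSON(
        vqc_params_to_json(w$vqc), simplifyVector = FALSE)
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a trained head from JSON
#'
#' @param path Path written by [save_head()].
#' @return A `trained_head`.
#' @export
load_head <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- do.call(head_config, obj$config[c("in_dim", "n_qubits", "n_layers",
                                           "head_kind", "shots", "embedding",
                                           "entangler")])
  trc <- do.call(train_config, obj$training)
  w <- list(W_in = as_matrix_json(obj$weights$W_in),
            b_in = as.numeric(obj$weights$b_in),
            W_out = as_matrix_json(obj$weights$W_out),
            b_out = as.numeric(obj$weights$b_out))
  if (cfg$head_kind == "vqc") {
    w$vqc <- vqc_params_from_json(jsonlite::toJSON(obj$weights$vqc,
                                                   auto_unbox = TRUE,
                                                   digits = NA))
  } else {
    w$W_mid <- as_matrix_json(obj$weights$W_mid)
    w$b_mid <- as.numeric(obj$weights$b_mid)
  }
  structure(list(config = cfg, training = trc, weights = w,
                 curves = tibble::as_tibble(obj$curves),
                 feature_names = obj$feature_names),
            class = "trained_head")
}

# jsonlite may return a matrix or a list of rows; coerce to matrix
as_matrix_json <- function(x) {
  if (is.matrix(x)) return(x)
  do.call(rbind, lapply(x, as.numeric))
}
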