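# Seeded synthetic two-class feature generator. It emulates the penultimate
# feature vectors a vision backbone would hand to the classifier head —
# low-dimensional real vectors whose class-conditional distributions have a
# controllable separation — so the head can be trained and compared without
# any imaging data.

#' Specify a synthetic two-class feature dataset
#'
#' `gaussian_blobs` draws unit-covariance Gaussians whose class means are
#' `separation` apart along the first feature axis (so `separation` is the
#' Mahalanobis distance between the classes). `ring_vs_disc` places class 0
#' in a Gaussian disc at the origin of the first two features and class 1
#' on a ring of radius `separation` (a nonlinearly separable pair);
#' remaining features are pure noise.
#'
#' @param n_train,n_val,n_test Samples per split; splits are independent
#'   draws, hence disjoint by construction.
#' @param n_features Feature dimension (the head's `in_dim`).
#' @param class_balance Probability of class 1, in (0, 1).
#' @param separation Nonnegative class separation (see above).
#' @param noise_kind `"gaussian_blobs"` or `"ring_vs_disc"`.
#' @param label_noise Fraction of labels flipped at random, in [0, 0.5).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the spec.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_train = 400L, n_val = 400L, n_test = 400L,
                           n_features = 8L, class_balance = 0.5,
                           separation = 6,
                           noise_kind = c("gaussian_blobs", "ring_vs_disc"),
                           label_noise = 0, seed = 0L) {
  noise_kind <- match.arg(noise_kind)
  if (separation < 0) stop("separation must be nonnegative", call. = FALSE)
  if (class_balance <= 0 || class_balance >= 1) {
    stop("class_balance must lie in (0, 1)", call. = FALSE)
  }
  if (label_noise < 0 || label_noise >= 0.5) {
    stop("label_noise must lie in [0, 0.5)", call. = FALSE)
  }
  structure(list(n_train = as.integer(n_train), n_val = as.integer(n_val),
                 n_test = as.integer(n_test),
                 n_features = as.integer(n_features),
                 class_balance = class_balance, separation = separation,
                 noise_kind = noise_kind, label_noise = label_noise,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

draw_split <- function(spec, n, seed) {
  with_seed_local(seed, {
    y <- as.integer(stats::runif(n) < spec$class_balance)
    p <- spec$n_features
    x <- matrix(stats::rnorm(n * p), n, p)
    if (spec$noise_kind == "gaussian_blobs") {
      x[, 1] <- x[, 1] + spec$separation * y
    } else {
      ang <- stats::runif(n, 0, 2 * pi)
      r <- ifelse(y == 1, spec$separation, 0)
      x[, 1] <- x[, 1] + r * cos(ang)
      x[, 2] <- x[, 2] + r * sin(ang)
    }
    if (spec$label_noise > 0) {
      flip <- stats::runif(n) < spec$label_noise
      y[flip] <- 1L - y[flip]
    }
    out <- tibble::as_tibble(as.data.frame(x))
    names(out) <- paste0("f", seq_len(p))
    out$label <- y
    out
  })
}

#' Generate one synthetic split
#'
#' @param spec A [synthetic_spec()].
#' @param split `"train"`, `"val"` or `"test"`; each split uses its own
#'   seed stream derived from `spec$seed`, so splits are independent.
#' @return A tibble of features `f1..fp` plus `label`.
#' @export
generate_dataset <- function(spec, split = c("train", "val", "test")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  split <- match.arg(split)
  off <- match(split, c("train", "val", "test"))
  n <- spec[[paste0("n_", split)]]
  draw_split(spec, n, (as.numeric(spec$seed) * 7 + off) %% 2147483647)
}

#' Generate all three splits
#'
#' @param spec A [synthetic_spec()].
#' @return Named list of tibbles: `train`, `val`, `test`.
#' @export
generate_splits <- function(spec) {
  list(train = generate_dataset(spec, "train"),
       val = generate_dataset(spec, "val"),
       test = generate_dataset(spec, "test"))
}

#' Write a feature table to CSV
#'
#' Deterministic plain-text output: same data, same bytes.
#'
#' @param data Tibble from [generate_dataset()] (or any data frame).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dataset_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
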