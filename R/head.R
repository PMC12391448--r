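# The hybrid classification head: Linear(in_dim -> M) -> middle block ->
# Linear(N -> 2). The middle block is either the VQC (angle/amplitude
# embedding + variational layers + Pauli-Z readout) or a matched fully
# connected N x N linear map, so the two heads differ only in the block the
# quantum circuit replaces.

#' Configure a classification head
#'
#' For the `"angle"` embedding the middle width equals `n_qubits` (one
#' feature per qubit); for `"amplitude"` it is `2^n_qubits`. The `"fc"` head
#' ignores the quantum fields and uses an N x N linear middle block with
#' bias.
#'
#' @param in_dim Input feature dimension (the backbone's penultimate width).
#' @param n_qubits Qubits in the middle block (8 or 16 are the reference
#'   settings).
#' @param n_layers Variational layers K (default 2).
#' @param head_kind `"vqc"` or `"fc"`.
#' @param shots 0 for exact (analytic) expectations; a positive count
#'   switches inference to Monte-Carlo measurement with that many shots
#'   (1000 being the reference hardware setting).
#' @param embedding `"angle"` (default) or `"amplitude"`.
#' @param entangler `"ring"` or `"chain"` CZ topology.
#' @return A `head_config` object.
#' @export
head_config <- function(in_dim, n_qubits = 8L, n_layers = 2L,
                        head_kind = c("vqc", "fc"), shots = 0L,
                        embedding = c("angle", "amplitude"),
                        entangler = c("ring", "chain")) {
  head_kind <- match.arg(head_kind)
  embedding <- match.arg(embedding)
  entangler <- match.arg(entangler)
  in_dim <- as.integer(in_dim); n_qubits <- as.integer(n_qubits)
  n_layers <- as.integer(n_layers); shots <- as.integer(shots)
  stopifnot(in_dim >= 1L, n_qubits >= 1L, n_layers >= 1L, shots >= 0L)
  mid_dim <- if (embedding == "amplitude") 2L^n_qubits else n_qubits
  structure(list(in_dim = in_dim, n_qubits = n_qubits, n_layers = n_layers,
                 head_kind = head_kind, shots = shots, embedding = embedding,
                 entangler = entangler, mid_dim = mid_dim),
            class = "head_config")
}

#' @export
print.head_config <- function(x, ...) {
  cat("<head_config> ", x$head_kind, " head: ", x$in_dim, " -> ",
      x$mid_dim, " -> 2", sep = "")
  if (x$head_kind == "vqc") {
    cat("; ", x$n_qubits, " qubits, K = ", x$n_layers, ", ", x$embedding,
        " embedding, shots = ", x$shots, sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Middle-block trainable parameter counts
#'
#' Returns the VQC angle count `3*K*N`, the FC weight count `N^2` (plus `N`
#' bias terms, reported separately since the headline comparison counts
#' weights only), and the weight-only reduction fraction.
#'
#' @param n_qubits N.
#' @param n_layers K.
#' @return A tibble with one row.
#' @examples
#' middle_block_params(16, 2)  # 96 vs 256 weights: 62.5% fewer
#' @export
middle_block_params <- function(n_qubits, n_layers = 2L) {
  vqc <- count_params(n_qubits, n_layers)
  fc_w <- as.integer(n_qubits)^2L
  storage.mode(fc_w) <- "integer"
  tibble::tibble(
    n_qubits = as.integer(n_qubits),
    n_layers = as.integer(n_layers),
    vqc_params = vqc,
    fc_weights = fc_w,
    fc_bias = as.integer(n_qubits),
    reduction_pct = 100 * (1 - vqc / fc_w)
  )
}

# --- weights ---------------------------------------------------------------

init_linear <- function(n_out, n_in) {
  matrix(stats::rnorm(n_out * n_in, sd = 1 / sqrt(n_in)), n_out, n_in)
}

#' Initialize head weights
#'
#' Linear maps get `N(0, 1/fan_in)` weights and zero biases; VQC angles get
#' small `N(0, 0.1)` values so the circuit starts near the identity and the
#' initial middle output is close to the embedding's Z profile.
#'
#' @param config A [head_config()].
#' @return A list of weights (`W_in`, `b_in`, middle block, `W_out`,
#'   `b_out`).
#' @export
init_head_weights <- function(config) {
  stopifnot(inherits(config, "head_config"))
  w <- list(
    W_in = init_linear(config$mid_dim, config$in_dim),
    b_in = numeric(config$mid_dim),
    W_out = init_linear(2L, config$n_qubits),
    b_out = numeric(2L)
  )
  if (config$head_kind == "vqc") {
    w$vqc <- vqc_params(
      config$n_qubits, config$n_layers,
      array(stats::rnorm(3L * config$n_layers * config$n_qubits, sd = 0.1),
            c(config$n_layers, config$n_qubits, 3L)),
      entangler = config$entangler)
  } else {
    w$W_mid <- init_linear(config$n_qubits, config$n_qubits)
    w$b_mid <- numeric(config$n_qubits)
  }
  w
}

# middle-block forward for the vqc head; returns list(m, state)
vqc_middle_forward <- function(config, weights, z, shots = 0L, seed = NULL) {
  n <- config$n_qubits
  if (config$embedding == "angle") {
    kern <- head_kernel(n, weights$vqc$entangler)
    fw <- vqc_fast_forward(kern, atan(z), weights$vqc$angles)
    amp <- fw$amp
    m <- fw$m
  } else {
    st <- amplitude_embed(z)
    amp <- run_circuit(variational_circuit(weights$vqc), st)$amplitudes
    m <- NULL
  }
  state <- pure_state(amp, n, normalize = FALSE)
  if (shots > 0L) {
    m <- expectations_from_histogram(sample_shots(state, shots, seed = seed))
  } else if (is.null(m)) {
    m <- pauli_z_expectations(state)
  }
  list(m = m, state = state)
}

#' Forward pass of a classification head
#'
#' Computes `logits = W_out %*% g(W_in %*% features + b_in) + b_out`, where
#' `g` is the embedded VQC readout (vqc head) or the linear middle block
#' (fc head).
#'
#' @param config A [head_config()].
#' @param weights Weights from [init_head_weights()] (or a trained model's
#'   `weights`).
#' @param features Numeric vector of length `in_dim`.
#' @param shots Override the config's shot count (`NULL` keeps it).
#' @param seed Optional seed for shot sampling.
#' @return List with `logits` (length 2), `middle` (the middle-block
#'   output), and `prob` (softmax probability of class 1).
#' @export
head_forward <- function(config, weights, features, shots = NULL,
                         seed = NULL) {
  stopifnot(inherits(config, "head_config"))
  features <- as.numeric(features)
  if (length(features) != config$in_dim) {
    stop("expected ", config$in_dim, " features, got ", length(features),
         call. = FALSE)
  }
  if (is.null(shots)) shots <- config$shots
  z <- as.numeric(weights$W_in %*% features + weights$b_in)
  m <- if (config$head_kind == "vqc") {
    vqc_middle_forward(config, weights, z, shots = shots, seed = seed)$m
  } else {
    as.numeric(weights$W_mid %*% z + weights$b_mid)
  }
  logits <- as.numeric(weights$W_out %*% m + weights$b_out)
  list(logits = logits, middle = m, prob = softmax2(logits)[2])
}

#' Label-smoothed cross-entropy for two classes
#'
#' With smoothing `s`, the target distribution puts `1 - s/2` on the true
#' class and `s/2` on the other, and the loss is the cross-entropy between
#' that target and the softmax of the logits.
#'
#' @param logits Numeric length-2 vector.
#' @param label 0 or 1.
#' @param label_smoothing Smoothing `s` in `[0, 1)`.
#' @return Nonnegative scalar loss.
#' @examples
#' head_loss(c(0, 0), 1)  # log(2)
#' @export
head_loss <- function(logits, label, label_smoothing = 0.1) {
  stopifnot(length(logits) == 2L, all(is.finite(logits)),
            label %in% c(0, 1), label_smoothing >= 0, label_smoothing < 1)
  lp <- log_softmax2(logits)
  t1 <- if (label == 1) 1 - label_smoothing / 2 else label_smoothing / 2
  -( (1 - t1) * lp[1] + t1 * lp[2] )
}

# loss + full gradient for one sample (analytic mode). Returns
# list(loss, grads) with grads mirroring the weight list.
head_grad <- function(config, weights, features, label,
                      label_smoothing = 0.1) {
  x <- as.numeric(features)
  z <- as.numeric(weights$W_in %*% x + weights$b_in)
  n <- config$n_qubits
  if (config$head_kind == "vqc") {
    if (config$embedding != "angle") {
      stop("training supports the angle embedding", call. = FALSE)
    }
    kern <- head_kernel(n, weights$vqc$entangler)
    a <- atan(z)
    fw <- vqc_fast_forward(kern, a, weights$vqc$angles)
    m <- fw$m
  } else {
    m <- as.numeric(weights$W_mid %*% z + weights$b_mid)
  }
  logits <- as.numeric(weights$W_out %*% m + weights$b_out)
  loss <- head_loss(logits, label, label_smoothing)

  p <- softmax2(logits)
  t1 <- if (label == 1) 1 - label_smoothing / 2 else label_smoothing / 2
  dlogits <- p - c(1 - t1, t1)
  g <- list(
    W_out = dlogits %o% m,
    b_out = dlogits
  )
  dm <- as.numeric(crossprod(weights$W_out, dlogits))
  if (config$head_kind == "fc") {
    g$W_mid <- dm %o% z
    g$b_mid <- dm
    dz <- as.numeric(crossprod(weights$W_mid, dm))
  } else {
    bw <- vqc_fast_backward(kern, a, weights$vqc$angles, fw$amp, dm)
    g$vqc <- bw$gvqc
    dz <- bw$ga / (1 + z^2)
  }
  g$W_in <- dz %o% x
  g$b_in <- dz
  list(loss = loss, grads = g, logits = logits)
}
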