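# Classical-to-quantum feature encodings: angle (arctan-squashed, one feature
# per qubit), amplitude (L2-normalized vector as amplitudes), and basis
# (bitstring) embedding.

check_features <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 1L || any(!is.finite(x))) {
    stop("features must be a non-empty finite numeric vector", call. = FALSE)
  }
  x
}

#' Circuit for the arctan angle embedding
#'
#' One feature per qubit. Each feature \eqn{x_i} is squashed to
#' \eqn{x'_i = \arctan(x_i) \in (-\pi/2, \pi/2)}, then qubit i receives
#' `H`, `RY(x'_i)` and `RZ((x'_i)^2)` in that order — the squared-angle RZ
#' is a deliberate extra nonlinearity of the encoding.
#'
#' @param features Numeric vector, one entry per qubit.
#' @return A [circuit_spec()] on `length(features)` qubits.
#' @export
angle_embedding_circuit <- function(features) {
  x <- check_features(features)
  n <- length(x)
  a <- atan(x)
  ops <- vector("list", 3L * n)
  for (i in seq_len(n)) {
    q <- i - 1L
    ops[[3L * i - 2L]] <- gate_op("H", q)
    ops[[3L * i - 1L]] <- gate_op("RY", q, a[i])
    ops[[3L * i]]      <- gate_op("RZ", q, a[i]^2)
  }
  circuit_spec(n, ops)
}

#' Angle embedding of a feature vector
#'
#' Encodes `n_qubits` real features into an `n_qubits`-qubit product state
#' by running [angle_embedding_circuit()] on the all-zeros state. The
#' per-qubit Pauli-Z profile of the result is \eqn{-\sin(\arctan x_i)}.
#'
#' @param features Numeric vector of finite features.
#' @param n_qubits Number of qubits; must equal `length(features)`.
#' @return A [pure_state()].
#' @examples
#' pauli_z_expectations(angle_embed(c(0, 1), 2))
#' @export
angle_embed <- function(features, n_qubits = length(features)) {
  x <- check_features(features)
  if (length(x) != n_qubits) {
    stop("angle embedding needs one feature per qubit: got ", length(x),
         " features for ", n_qubits, " qubits", call. = FALSE)
  }
  run_circuit(angle_embedding_circuit(x))
}

#' Amplitude embedding of a feature vector
#'
#' L2-normalizes the vector and writes it directly into the amplitudes of a
#' \eqn{\lceil \log_2 N \rceil}-qubit state, zero-padding to the next power
#' of two. Amplitudes are assigned directly rather than through a state
#' preparation circuit; the O(N)-depth circuit this encoding would need on
#' hardware is the reason it is treated as simulator-only.
#'
#' @param features Numeric vector with nonzero L2 norm.
#' @return A [pure_state()] on `max(1, ceiling(log2(length(features))))`
#'   qubits.
#' @examples
#' amplitude_embed(c(3, 4))
#' @export
amplitude_embed <- function(features) {
  x <- check_features(features)
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) {
    stop("amplitude embedding is undefined for the all-zero vector",
         call. = FALSE)
  }
  n_qubits <- max(1L, as.integer(ceiling(log2(length(x)))))
  amp <- complex(2^n_qubits)
  amp[seq_along(x)] <- x / nrm
  pure_state(amp, n_qubits)
}

#' Basis embedding of a bit vector
#'
#' Maps a binary vector to the corresponding computational basis state,
#' little-endian: `bits[1]` is qubit 0, the least-significant bit of the
#' basis index.
#'
#' @param bits Vector with entries in `{0, 1}`.
#' @return A [pure_state()] on `length(bits)` qubits.
#' @examples
#' basis_embed(c(1, 0, 1))  # amplitude 1 at index 5
#' @export
basis_embed <- function(bits) {
  b <- as.numeric(bits)
  if (length(b) < 1L || any(!(b %in% c(0, 1)))) {
    stop("bits must be a non-empty vector with entries in {0, 1}",
         call. = FALSE)
  }
  n <- length(b)
  amp <- complex(2^n)
  amp[sum(b * 2^(seq_len(n) - 1L)) + 1L] <- 1 + 0i
  pure_state(amp, n)
}

#' Embed features with a named scheme
#'
#' Dispatch helper used by the hybrid head and the command-line front-end.
#'
#' @param features Numeric vector.
#' @param scheme One of `"angle"`, `"amplitude"`, `"basis"`.
#' @return A [pure_state()].
#' @export
embed_features <- function(features, scheme = c("angle", "amplitude", "basis")) {
  scheme <- match.arg(scheme)
  switch(scheme,
         angle = angle_embed(features),
         amplitude = amplitude_embed(features),
         basis = basis_embed(features))
}

#' Read a feature table from CSV
#'
#' One row per sample. When `label_col` is given (or a column named
#' `label` exists) it is split off as the binary label.
#'
#' @param path CSV path; a header row is optional (detected from the first
#'   field being non-numeric).
#' @param label_col Name or index of the label column, `NULL` for none.
#' @return A tibble of numeric features, with a `label` column when present.
#' @export
read_feature_csv <- function(path, label_col = NULL) {
  first <- utils::read.csv(path, header = FALSE, nrows = 1L)
  has_header <- any(is.na(suppressWarnings(as.numeric(unlist(first)))))
  df <- utils::read.csv(path, header = has_header)
  if (!has_header) names(df) <- c(paste0("f", seq_len(ncol(df))))
  df <- tibble::as_tibble(df)
  if (is.null(label_col) && "label" %in% names(df)) label_col <- "label"
  if (!is.null(label_col)) {
    lab <- df[[label_col]]
    df <- df[setdiff(names(df), if (is.numeric(label_col))
      names(df)[label_col] else label_col)]
    df$label <- as.integer(lab)
  }
  df
}
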