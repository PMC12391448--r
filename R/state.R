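# Dense n-qubit statevector simulation for the gate set {H, RY, RZ, U3, CZ}.
#
# Qubit ordering is little-endian throughout: qubit 0 is the least-significant
# bit of the integer index of a computational basis state, so |q2 q1 q0> with
# q0 = 1 sits at index 1. Bitstrings rendered as text put qubit 0 first
# (character j of a key is the bit of qubit j - 1).

MAX_QUBITS <- 24L

#' Construct a pure n-qubit state
#'
#' A `pure_state` holds the full complex amplitude vector of an n-qubit
#' register, length `2^n_qubits`, unit L2 norm. Qubit 0 is the
#' least-significant bit of the basis-state index (little-endian).
#'
#' @param amplitudes Complex (or numeric) vector of length `2^n_qubits`.
#' @param n_qubits Number of qubits; inferred from the length when `NULL`.
#' @param normalize If `TRUE`, rescale to unit norm instead of erroring on
#'   mildly non-normalized input.
#' @return An object of class `pure_state` with fields `n_qubits` and
#'   `amplitudes`.
#' @examples
#' pure_state(c(1, 0, 0, 1) / sqrt(2))
#' @export
pure_state <- function(amplitudes, n_qubits = NULL, normalize = FALSE) {
  amp <- as.complex(amplitudes)
  if (is.null(n_qubits)) {
    n_qubits <- as.integer(round(log2(length(amp))))
  }
  n_qubits <- as.integer(n_qubits)
  if (n_qubits < 1L || n_qubits > MAX_QUBITS) {
    stop("n_qubits must be in [1, ", MAX_QUBITS, "], got ", n_qubits,
         call. = FALSE)
  }
  if (length(amp) != 2^n_qubits) {
    stop("amplitude vector has length ", length(amp),
         " but 2^n_qubits = ", 2^n_qubits, call. = FALSE)
  }
  if (any(!is.finite(Re(amp))) || any(!is.finite(Im(amp)))) {
    stop("amplitudes must be finite", call. = FALSE)
  }
  nrm <- sqrt(sum(Mod(amp)^2))
  if (normalize) {
    if (nrm == 0) stop("cannot normalize the zero vector", call. = FALSE)
    amp <- amp / nrm
  } else if (abs(nrm - 1) > 1e-6) {
    stop("state is not normalized: ||amplitudes||_2 = ", format(nrm),
         call. = FALSE)
  }
  structure(list(n_qubits = n_qubits, amplitudes = amp),
            class = "pure_state")
}

#' @export
print.pure_state <- function(x, max_print = 8L, ...) {
  cat("<pure_state> ", x$n_qubits, " qubit(s), dim ", length(x$amplitudes),
      "\n", sep = "")
  p <- Mod(x$amplitudes)^2
  ord <- order(p, decreasing = TRUE)
  show <- ord[seq_len(min(max_print, sum(p > 1e-12)))]
  for (i in show) {
    cat(sprintf("  |%s>  amp % .5f%+.5fi  p=%.5f\n",
                basis_label(i - 1L, x$n_qubits),
                Re(x$amplitudes[i]), Im(x$amplitudes[i]), p[i]))
  }
  invisible(x)
}

# bitstring label with qubit 0 as the first character
basis_label <- function(index, n_qubits) {
  bits <- bitwAnd(bitwShiftR(index, 0:(n_qubits - 1L)), 1L)
  paste(bits, collapse = "")
}

basis_index <- function(label) {
  bits <- as.integer(strsplit(label, "")[[1]])
  sum(bits * 2^(seq_along(bits) - 1L))
}

#' All-zeros computational basis state
#'
#' Returns \eqn{|0\rangle^{\otimes n}}: amplitude 1 on basis index 0.
#' Capacity is capped at 24 qubits (a 128 MiB complex vector) to fail fast on
#' accidentally large registers.
#'
#' @param n_qubits Number of qubits, between 1 and 24.
#' @return A [pure_state()].
#' @examples
#' zero_state(2)
#' @export
zero_state <- function(n_qubits) {
  n_qubits <- as.integer(n_qubits)
  if (length(n_qubits) != 1L || is.na(n_qubits) ||
      n_qubits < 1L || n_qubits > MAX_QUBITS) {
    stop("n_qubits must be a single integer in [1, ", MAX_QUBITS, "]",
         call. = FALSE)
  }
  amp <- complex(2^n_qubits)
  amp[1L] <- 1 + 0i
  pure_state(amp, n_qubits)
}

#' Construct a gate operation
#'
#' @param kind One of `"H"`, `"RY"`, `"RZ"`, `"U3"`, `"CZ"`.
#' @param targets Qubit indices (0-based). `CZ` takes exactly two distinct
#'   targets, all other gates exactly one.
#' @param angles Rotation angles in radians: none for `H`/`CZ`, one for
#'   `RY`/`RZ`, three (theta, phi, lambda) for `U3`.
#' @return An object of class `gate_op`.
#' @examples
#' gate_op("U3", 0, c(pi / 2, 0, pi))
#' gate_op("CZ", c(0, 1))
#' @export
gate_op <- function(kind, targets, angles = numeric(0)) {
  kind <- match.arg(kind, c("H", "RY", "RZ", "U3", "CZ"))
  targets <- as.integer(targets)
  angles <- as.numeric(angles)
  n_t <- if (kind == "CZ") 2L else 1L
  n_a <- switch(kind, H = 0L, CZ = 0L, RY = 1L, RZ = 1L, U3 = 3L)
  if (length(targets) != n_t || anyDuplicated(targets) || any(targets < 0L)) {
    stop(kind, " expects ", n_t, " distinct nonnegative target(s)",
         call. = FALSE)
  }
  if (length(angles) != n_a || any(!is.finite(angles))) {
    stop(kind, " expects ", n_a, " finite angle(s)", call. = FALSE)
  }
  structure(list(kind = kind, targets = targets, angles = angles),
            class = "gate_op")
}

#' @export
print.gate_op <- function(x, ...) {
  cat("<gate_op> ", x$kind, "(",
      if (length(x$angles)) paste(signif(x$angles, 6), collapse = ", ") else "",
      ") on q", paste(x$targets, collapse = ",q"), "\n", sep = "")
  invisible(x)
}

#' Construct an ordered circuit
#'
#' A `circuit_spec` is an ordered list of [gate_op()]s on a register of
#' `n_qubits`; [run_circuit()] applies them left to right.
#'
#' @param n_qubits Register size.
#' @param ops List of [gate_op()] objects; every target must be `< n_qubits`.
#' @return An object of class `circuit_spec`.
#' @export
circuit_spec <- function(n_qubits, ops = list()) {
  n_qubits <- as.integer(n_qubits)
  if (n_qubits < 1L) stop("n_qubits must be positive", call. = FALSE)
  for (op in ops) {
    if (!inherits(op, "gate_op")) stop("ops must be gate_op objects",
                                       call. = FALSE)
    if (any(op$targets >= n_qubits)) {
      stop("gate ", op$kind, " targets qubit ", max(op$targets),
           " but the register has only ", n_qubits, " qubits", call. = FALSE)
    }
  }
  structure(list(n_qubits = n_qubits, ops = ops), class = "circuit_spec")
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat("<circuit_spec> ", x$n_qubits, " qubits, ", length(x$ops), " ops\n",
      sep = "")
  invisible(x)
}

#' Unitary matrix of a gate
#'
#' Rotation conventions (OpenQASM 2.0):
#' \deqn{RY(\theta) = \begin{pmatrix}\cos\theta/2 & -\sin\theta/2\\
#'   \sin\theta/2 & \cos\theta/2\end{pmatrix}, \quad
#'   RZ(\theta) = \mathrm{diag}(e^{-i\theta/2}, e^{i\theta/2})}
#' \deqn{U3(\theta,\phi,\lambda) = \begin{pmatrix}
#'   \cos\theta/2 & -e^{i\lambda}\sin\theta/2\\
#'   e^{i\phi}\sin\theta/2 & e^{i(\phi+\lambda)}\cos\theta/2\end{pmatrix}}
#' so that `U3` equals `RZ(phi) RY(theta) RZ(lambda)` up to global phase.
#'
#' @param op A [gate_op()].
#' @return A 2x2 (or 4x4 for `CZ`) complex unitary matrix.
#' @examples
#' gate_matrix(gate_op("H", 0))
#' @export
gate_matrix <- function(op) {
  if (!inherits(op, "gate_op")) stop("op must be a gate_op", call. = FALSE)
  a <- op$angles
  switch(op$kind,
    H = matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2) + 0i,
    RY = {
      c2 <- cos(a[1] / 2); s2 <- sin(a[1] / 2)
      matrix(c(c2, s2, -s2, c2), 2, 2) + 0i
    },
    RZ = diag(c(exp(-1i * a[1] / 2), exp(1i * a[1] / 2))),
    U3 = u3_matrix(a[1], a[2], a[3]),
    CZ = diag(c(1, 1, 1, -1)) + 0i,
    stop("unsupported gate kind: ", op$kind, call. = FALSE)
  )
}

u3_matrix <- function(theta, phi, lambda) {
  c2 <- cos(theta / 2); s2 <- sin(theta / 2)
  matrix(c(c2 + 0i,
           exp(1i * phi) * s2,
           -exp(1i * lambda) * s2,
           exp(1i * (phi + lambda)) * c2),
         2, 2)
}

# --- cached index machinery ------------------------------------------------

.sv_cache <- new.env(parent = emptyenv())

# 1-based indices of basis states whose bit `target` is 0, for an n-qubit
# register; the partner index (bit = 1) is i0 + 2^target.
bit0_indices <- function(n_qubits, target) {
  key <- paste0(n_qubits, ".", target)
  idx <- .sv_cache[[key]]
  if (is.null(idx)) {
    all_i <- 0:(2^n_qubits - 1L)
    idx <- which(bitwAnd(all_i, bitwShiftL(1L, target)) == 0L)
    .sv_cache[[key]] <- idx
  }
  idx
}

# indices (1-based) where both bits are 1, for CZ
bit11_indices <- function(n_qubits, t1, t2) {
  key <- paste0("cz", n_qubits, ".", min(t1, t2), ".", max(t1, t2))
  idx <- .sv_cache[[key]]
  if (is.null(idx)) {
    mask <- bitwOr(bitwShiftL(1L, t1), bitwShiftL(1L, t2))
    all_i <- 0:(2^n_qubits - 1L)
    idx <- which(bitwAnd(all_i, mask) == mask)
    .sv_cache[[key]] <- idx
  }
  idx
}

# n x 2^n sign matrix: entry [i, b] = +1 if bit (i-1) of (b-1) is 0 else -1
z_sign_matrix <- function(n_qubits) {
  key <- paste0("z", n_qubits)
  s <- .sv_cache[[key]]
  if (is.null(s)) {
    all_i <- 0:(2^n_qubits - 1L)
    s <- vapply(0:(n_qubits - 1L), function(q) {
      1 - 2 * bitwAnd(bitwShiftR(all_i, q), 1L)
    }, numeric(2^n_qubits))
    s <- t(s)  # n x 2^n
    .sv_cache[[key]] <- s
  }
  s
}

# apply a 2x2 matrix to qubit `target` of a raw amplitude vector
apply_1q_raw <- function(amp, n_qubits, target, m) {
  i0 <- bit0_indices(n_qubits, target)
  i1 <- i0 + bitwShiftL(1L, target)
  a0 <- amp[i0]; a1 <- amp[i1]
  amp[i0] <- m[1, 1] * a0 + m[1, 2] * a1
  amp[i1] <- m[2, 1] * a0 + m[2, 2] * a1
  amp
}

apply_cz_raw <- function(amp, n_qubits, t1, t2) {
  i11 <- bit11_indices(n_qubits, t1, t2)
  amp[i11] <- -amp[i11]
  amp
}

apply_op_raw <- function(amp, n_qubits, op) {
  if (op$kind == "CZ") {
    apply_cz_raw(amp, n_qubits, op$targets[1], op$targets[2])
  } else {
    apply_1q_raw(amp, n_qubits, op$targets[1], gate_matrix(op))
  }
}

# --- public gate application ----------------------------------------------

#' Apply a gate to a state
#'
#' Returns a new [pure_state()]; the input is untouched. The action equals
#' multiplication by the full Kronecker-product matrix of the gate padded
#' with identities, without ever forming that matrix.
#'
#' @param state A [pure_state()].
#' @param op A [gate_op()] whose targets lie in `[0, n_qubits)`.
#' @return The transformed [pure_state()].
#' @examples
#' apply_gate(zero_state(1), gate_op("H", 0))
#' @export
apply_gate <- function(state, op) {
  stopifnot(inherits(state, "pure_state"), inherits(op, "gate_op"))
  if (any(op$targets >= state$n_qubits)) {
    stop("target qubit out of range for a ", state$n_qubits,
         "-qubit state", call. = FALSE)
  }
  amp <- apply_op_raw(state$amplitudes, state$n_qubits, op)
  structure(list(n_qubits = state$n_qubits, amplitudes = amp),
            class = "pure_state")
}

#' Run a circuit on an initial state
#'
#' Applies the ops of `spec` left to right.
#'
#' @param spec A [circuit_spec()].
#' @param initial A [pure_state()] on the same register; defaults to
#'   [zero_state()].
#' @return The final [pure_state()].
#' @export
run_circuit <- function(spec, initial = zero_state(spec$n_qubits)) {
  stopifnot(inherits(spec, "circuit_spec"), inherits(initial, "pure_state"))
  if (initial$n_qubits != spec$n_qubits) {
    stop("initial state has ", initial$n_qubits,
         " qubits but the circuit expects ", spec$n_qubits, call. = FALSE)
  }
  amp <- initial$amplitudes
  for (op in spec$ops) amp <- apply_op_raw(amp, spec$n_qubits, op)
  structure(list(n_qubits = spec$n_qubits, amplitudes = amp),
            class = "pure_state")
}

#' Per-qubit Pauli-Z expectation values
#'
#' For each qubit i, \eqn{\langle Z_i \rangle = P(\mathrm{bit}_i = 0) -
#' P(\mathrm{bit}_i = 1)}, computed from the exact amplitudes. This vector of
#' expectations is the real-valued readout of the classifier circuit.
#'
#' @param state A normalized [pure_state()] (norm checked to 1e-6).
#' @return Numeric vector of length `n_qubits`, entries in `[-1, 1]`.
#' @examples
#' pauli_z_expectations(zero_state(3))
#' @export
pauli_z_expectations <- function(state) {
  stopifnot(inherits(state, "pure_state"))
  p <- Mod(state$amplitudes)^2
  if (abs(sum(p) - 1) > 1e-6) {
    stop("state is not normalized (|p|_1 = ", format(sum(p)), ")",
         call. = FALSE)
  }
  as.numeric(z_sign_matrix(state$n_qubits) %*% p)
}

# squared-norm helper used by invariants/tests
state_norm <- function(state) sqrt(sum(Mod(state$amplitudes)^2))
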