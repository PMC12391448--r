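# Independent brute-force oracles the implementation is checked against.
# These deliberately use the naive dense route: build the full 2^n x 2^n
# Kronecker-product matrix of every gate and multiply.

# full-register matrix of a gate, little-endian (qubit 0 = least
# significant bit of the basis index, i.e. the innermost Kronecker factor)
oracle_gate_matrix <- function(op, n_qubits) {
  if (op$kind == "CZ") {
    idx <- 0:(2^n_qubits - 1L)
    mask <- bitwOr(bitwShiftL(1L, op$targets[1]), bitwShiftL(1L, op$targets[2]))
    return(diag(ifelse(bitwAnd(idx, mask) == mask, -1, 1)) + 0i)
  }
  t <- op$targets[1]
  m <- gate_matrix(op)
  left <- diag(2^(n_qubits - 1L - t)) + 0i
  right <- diag(2^t) + 0i
  left %x% m %x% right
}

# run a circuit by dense matrix multiplication
oracle_run_circuit <- function(spec, initial) {
  amp <- initial$amplitudes
  for (op in spec$ops) {
    amp <- as.vector(oracle_gate_matrix(op, spec$n_qubits) %*% amp)
  }
  amp
}

random_gate <- function(n_qubits) {
  kind <- sample(c("H", "RY", "RZ", "U3", "CZ"), 1)
  if (kind == "CZ" && n_qubits >= 2) {
    gate_op("CZ", sample.int(n_qubits, 2) - 1L)
  } else if (kind == "CZ") {
    gate_op("H", 0L)
  } else {
    n_a <- switch(kind, H = 0L, RY = 1L, RZ = 1L, U3 = 3L)
    gate_op(kind, sample.int(n_qubits, 1) - 1L, stats::runif(n_a, -pi, pi))
  }
}

random_circuit <- function(n_qubits, n_gates) {
  circuit_spec(n_qubits, lapply(seq_len(n_gates),
                                function(i) random_gate(n_qubits)))
}

random_state <- function(n_qubits) {
  amp <- complex(real = stats::rnorm(2^n_qubits),
                 imaginary = stats::rnorm(2^n_qubits))
  pure_state(amp / sqrt(sum(Mod(amp)^2)), n_qubits)
}

# pairwise Mann-Whitney AUC: P(score_pos > score_neg) + 1/2 P(tie)
oracle_auc_mann_whitney <- function(labels, scores) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  total <- 0
  for (a in sp) total <- total + sum(a > sn) + 0.5 * sum(a == sn)
  total / (length(sp) * length(sn))
}

# central finite differences of f = <upstream, vqc_forward> wrt all angles
oracle_fd_grad <- function(params, embedded, upstream, h = 1e-5) {
  f <- function(p) sum(upstream * vqc_forward(p, embedded))
  g <- array(0, dim(params$angles))
  for (k in seq_len(params$n_layers)) {
    for (i in seq_len(params$n_qubits)) {
      for (j in 1:3) {
        pp <- params; pp$angles[k, i, j] <- pp$angles[k, i, j] + h
        pm <- params; pm$angles[k, i, j] <- pm$angles[k, i, j] - h
        g[k, i, j] <- (f(pp) - f(pm)) / (2 * h)
      }
    }
  }
  g
}

# states equal up to a global phase factor
expect_equal_up_to_phase <- function(a, b, tol = 1e-9) {
  i <- which.max(Mod(b))
  phase <- if (Mod(a[i]) > 1e-12) b[i] / a[i] else 1 + 0i
  expect_lt(max(Mod(a * phase - b)), tol)
}
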