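# Fast inner loop for the angle-embedded VQC head. Semantically identical
# to running the gate-object circuit (the generic path is kept and
# cross-checked in the tests); this path precomputes the per-qubit index
# sets once per register and differentiates each gate from four subspace
# inner products instead of full derivative-matrix applications.

head_kernel <- function(n_qubits, entangler) {
  key <- paste0("kern", n_qubits, entangler)
  k <- .sv_cache[[key]]
  if (!is.null(k)) return(k)
  dim <- 2L^n_qubits
  i0 <- lapply(0:(n_qubits - 1L), function(q) bit0_indices(n_qubits, q))
  i1 <- lapply(0:(n_qubits - 1L), function(q) {
    i0[[q + 1L]] + bitwShiftL(1L, q)
  })
  pairs <- entangler_pairs(n_qubits, entangler)
  cz <- lapply(pairs, function(p) bit11_indices(n_qubits, p[1], p[2]))
  k <- list(n = n_qubits, dim = dim, i0 = i0, i1 = i1, cz = cz,
            sgn = z_sign_matrix(n_qubits))
  .sv_cache[[key]] <- k
  k
}

# forward through H column + RY(a)/RZ(a^2) embedding + K variational layers;
# returns the final amplitudes and the Z-expectation vector
vqc_fast_forward <- function(kern, a, angles) {
  n <- kern$n
  K <- dim(angles)[1]
  amp <- rep(1 / sqrt(kern$dim), kern$dim) + 0i  # H column on |0...0>
  for (q in seq_len(n)) {
    j0 <- kern$i0[[q]]; j1 <- kern$i1[[q]]
    c2 <- cos(a[q] / 2); s2 <- sin(a[q] / 2)
    a0 <- amp[j0]; a1 <- amp[j1]
    amp[j0] <- c2 * a0 - s2 * a1
    amp[j1] <- s2 * a0 + c2 * a1
    ph <- exp(-0.5i * a[q]^2)
    amp[j0] <- amp[j0] * ph
    amp[j1] <- amp[j1] * Conj(ph)
  }
  for (k in seq_len(K)) {
    for (q in seq_len(n)) {
      m <- u3_matrix(angles[k, q, 1], angles[k, q, 2], angles[k, q, 3])
      j0 <- kern$i0[[q]]; j1 <- kern$i1[[q]]
      a0 <- amp[j0]; a1 <- amp[j1]
      amp[j0] <- m[1, 1] * a0 + m[1, 2] * a1
      amp[j1] <- m[2, 1] * a0 + m[2, 2] * a1
    }
    for (cz in kern$cz) amp[cz] <- -amp[cz]
  }
  list(amp = amp, m = as.numeric(kern$sgn %*% (Mod(amp)^2)))
}

# adjoint backward sweep for f = <amp_out| diag(d) |amp_out>; returns the
# gradient array for the U3 angles and the gradient wrt the embedding
# angles a (combining the RY(a) and RZ(a^2) contributions).
vqc_fast_backward <- function(kern, a, angles, amp_out, upstream) {
  n <- kern$n
  K <- dim(angles)[1]
  d <- as.numeric(crossprod(kern$sgn, upstream))
  lam <- d * amp_out
  amp <- amp_out
  gvqc <- array(0, dim(angles))
  undo_1q <- function(v, j0, j1, m) {
    # multiply by the conjugate transpose of m
    a0 <- v[j0]; a1 <- v[j1]
    v[j0] <- Conj(m[1, 1]) * a0 + Conj(m[2, 1]) * a1
    v[j1] <- Conj(m[1, 2]) * a0 + Conj(m[2, 2]) * a1
    v
  }
  for (k in rev(seq_len(K))) {
    for (cz in kern$cz) { amp[cz] <- -amp[cz]; lam[cz] <- -lam[cz] }
    for (q in rev(seq_len(n))) {
      th <- angles[k, q, 1]; ph <- angles[k, q, 2]; la <- angles[k, q, 3]
      m <- u3_matrix(th, ph, la)
      j0 <- kern$i0[[q]]; j1 <- kern$i1[[q]]
      amp <- undo_1q(amp, j0, j1, m)
      s00 <- sum(Conj(lam[j0]) * amp[j0])
      s01 <- sum(Conj(lam[j0]) * amp[j1])
      s10 <- sum(Conj(lam[j1]) * amp[j0])
      s11 <- sum(Conj(lam[j1]) * amp[j1])
      c2 <- cos(th / 2); s2 <- sin(th / 2)
      ep <- exp(1i * ph); el <- exp(1i * la); epl <- ep * el
      gvqc[k, q, 1] <- 2 * Re(0.5 * (-s2 * s00 - el * c2 * s01 +
                                       ep * c2 * s10 - epl * s2 * s11))
      gvqc[k, q, 2] <- 2 * Re(1i * ep * s2 * s10 + 1i * epl * c2 * s11)
      gvqc[k, q, 3] <- 2 * Re(-1i * el * s2 * s01 + 1i * epl * c2 * s11)
      lam <- undo_1q(lam, j0, j1, m)
    }
  }
  ga <- numeric(n)
  for (q in rev(seq_len(n))) {
    j0 <- kern$i0[[q]]; j1 <- kern$i1[[q]]
    # RZ(a^2)
    phz <- exp(-0.5i * a[q]^2)
    amp[j0] <- amp[j0] * Conj(phz); amp[j1] <- amp[j1] * phz
    s00 <- sum(Conj(lam[j0]) * amp[j0])
    s11 <- sum(Conj(lam[j1]) * amp[j1])
    g_rz <- 2 * Re(-0.5i * phz * s00 + 0.5i * Conj(phz) * s11)
    lam[j0] <- lam[j0] * Conj(phz); lam[j1] <- lam[j1] * phz
    # RY(a)
    c2 <- cos(a[q] / 2); s2 <- sin(a[q] / 2)
    a0 <- amp[j0]; a1 <- amp[j1]
    amp[j0] <- c2 * a0 + s2 * a1
    amp[j1] <- -s2 * a0 + c2 * a1
    s00 <- sum(Conj(lam[j0]) * amp[j0])
    s01 <- sum(Conj(lam[j0]) * amp[j1])
    s10 <- sum(Conj(lam[j1]) * amp[j0])
    s11 <- sum(Conj(lam[j1]) * amp[j1])
    g_ry <- 2 * Re(0.5 * (-s2 * s00 - c2 * s01 + c2 * s10 - s2 * s11))
    l0 <- lam[j0]; l1 <- lam[j1]
    lam[j0] <- c2 * l0 + s2 * l1
    lam[j1] <- -s2 * l0 + c2 * l1
    ga[q] <- g_ry + 2 * a[q] * g_rz
  }
  list(gvqc = gvqc, ga = ga)
}
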