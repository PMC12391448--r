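# Shot-based measurement and M3-style readout-error mitigation under a
# tensor-product noise model: each qubit has its own 2x2 column-stochastic
# confusion matrix P(measured | true), bits are flipped independently, and
# correction solves the tensor-product linear system restricted to the
# observed bitstrings and their single-bit-flip neighbors (the matrix-free
# idea, so cost stays O(shots * n) rather than O(4^n)).

#' Shot histogram
#'
#' Bitstring -> count map from repeated computational-basis measurement.
#' Keys are little-endian: character j is the bit of qubit j-1.
#'
#' @param counts Named nonnegative integer vector; names are bitstrings of
#'   length `n_qubits`.
#' @param n_qubits Register size (inferred from key length when `NULL`).
#' @return An object of class `shot_histogram` with `counts`, `shots`,
#'   `n_qubits`.
#' @export
shot_histogram <- function(counts, n_qubits = NULL) {
  counts <- counts[counts > 0]
  keys <- names(counts)
  if (is.null(keys) || any(!grepl("^[01]+$", keys))) {
    stop("counts must be named by 0/1 bitstrings", call. = FALSE)
  }
  if (is.null(n_qubits)) n_qubits <- nchar(keys[1])
  if (any(nchar(keys) != n_qubits)) {
    stop("all bitstrings must have length ", n_qubits, call. = FALSE)
  }
  cnt <- as.numeric(counts)
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  structure(list(n_qubits = as.integer(n_qubits),
                 counts = stats::setNames(cnt, keys),
                 shots = sum(cnt)),
            class = "shot_histogram")
}

#' @export
print.shot_histogram <- function(x, ...) {
  cat("<shot_histogram> ", x$n_qubits, " qubit(s), ", x$shots, " shots, ",
      length(x$counts), " distinct outcomes\n", sep = "")
  invisible(x)
}

#' Measure a state with a finite number of shots
#'
#' A seeded multinomial draw from the exact outcome probabilities
#' `|amplitude|^2` — the Monte-Carlo measurement a hardware run performs
#' (1000 shots being the reference setting).
#'
#' @param state A normalized [pure_state()].
#' @param shots Positive shot count.
#' @param seed Optional seed (the draw is deterministic under it; `NULL`
#'   uses and advances the caller's RNG stream).
#' @return A [shot_histogram()].
#' @export
sample_shots <- function(state, shots, seed = NULL) {
  stopifnot(inherits(state, "pure_state"))
  shots <- as.integer(shots)
  if (is.na(shots) || shots < 1L) {
    stop("shots must be a positive integer", call. = FALSE)
  }
  p <- Mod(state$amplitudes)^2
  if (abs(sum(p) - 1) > 1e-6) stop("state is not normalized", call. = FALSE)
  draw <- function() as.numeric(stats::rmultinom(1L, shots, p))
  cnt <- if (is.null(seed)) draw() else with_seed_local(seed, draw())
  nz <- which(cnt > 0)
  shot_histogram(stats::setNames(cnt[nz], vapply(nz - 1L, basis_label,
                                                 character(1),
                                                 n_qubits = state$n_qubits)),
                 state$n_qubits)
}

# keys -> 0/1 matrix (rows outcomes, cols qubits)
key_bit_matrix <- function(keys, n_qubits) {
  m <- matrix(0L, length(keys), n_qubits)
  for (j in seq_len(n_qubits)) m[, j] <- as.integer(substr(keys, j, j))
  m
}

#' Per-qubit Z expectations from measured counts
#'
#' Entry i is `(n_{bit_i = 0} - n_{bit_i = 1}) / shots`. Also accepts the
#' quasi-probability output of [mitigate()] (weights may then be negative,
#' but each entry stays the plug-in estimate of the expectation).
#'
#' @param hist A [shot_histogram()] or `mitigated_counts` object.
#' @return Numeric vector of length `n_qubits`, entries in `[-1, 1]` for
#'   genuine histograms.
#' @export
expectations_from_histogram <- function(hist) {
  if (inherits(hist, "mitigated_counts")) {
    w <- hist$quasi
    n <- hist$n_qubits
  } else {
    stopifnot(inherits(hist, "shot_histogram"))
    if (hist$shots <= 0) stop("empty histogram", call. = FALSE)
    w <- hist$counts / hist$shots
    n <- hist$n_qubits
  }
  bits <- key_bit_matrix(names(w), n)
  as.numeric(crossprod(1 - 2 * bits, w))
}

#' Per-qubit readout calibration
#'
#' One 2x2 column-stochastic confusion matrix per qubit, columns indexed by
#' the true bit and rows by the measured bit: column j is the distribution
#' of measured outcomes given true bit j.
#'
#' @param p0_to_1 Probability of reading 1 when the true bit is 0; recycled
#'   across qubits.
#' @param p1_to_0 Probability of reading 0 when the true bit is 1.
#' @param n_qubits Number of qubits.
#' @return An object of class `readout_calibration` (list of matrices).
#' @export
readout_calibration <- function(p0_to_1, p1_to_0 = p0_to_1, n_qubits = NULL) {
  if (is.null(n_qubits)) n_qubits <- max(length(p0_to_1), length(p1_to_0))
  p01 <- rep_len(as.numeric(p0_to_1), n_qubits)
  p10 <- rep_len(as.numeric(p1_to_0), n_qubits)
  if (any(p01 < 0 | p01 > 1 | p10 < 0 | p10 > 1)) {
    stop("flip probabilities must lie in [0, 1]", call. = FALSE)
  }
  mats <- lapply(seq_len(n_qubits), function(i) {
    matrix(c(1 - p01[i], p01[i], p10[i], 1 - p10[i]), 2, 2)
  })
  structure(list(n_qubits = as.integer(n_qubits), mats = mats),
            class = "readout_calibration")
}

#' Build a calibration from explicit confusion matrices
#'
#' @param mats List of per-qubit 2x2 column-stochastic matrices.
#' @return A `readout_calibration`.
#' @export
calibration_from_matrices <- function(mats) {
  for (m in mats) {
    if (!is.matrix(m) || !all(dim(m) == 2L) || any(m < 0) || any(m > 1) ||
        any(abs(colSums(m) - 1) > 1e-9)) {
      stop("each calibration matrix must be 2x2 column-stochastic",
           call. = FALSE)
    }
  }
  structure(list(n_qubits = length(mats), mats = mats),
            class = "readout_calibration")
}

#' Simulate readout noise on a histogram
#'
#' Each recorded shot has its bits independently flipped according to the
#' per-qubit confusion matrices; the shot total is preserved. This is the
#' synthetic stand-in for the measurement noise that calibration-based
#' mitigation corrects.
#'
#' @param hist A [shot_histogram()].
#' @param calib A [readout_calibration()] on the same register.
#' @param seed Optional seed.
#' @return A new [shot_histogram()].
#' @export
apply_readout_noise <- function(hist, calib, seed = NULL) {
  stopifnot(inherits(hist, "shot_histogram"),
            inherits(calib, "readout_calibration"))
  if (hist$n_qubits != calib$n_qubits) {
    stop("histogram and calibration register sizes differ", call. = FALSE)
  }
  n <- hist$n_qubits
  run <- function() {
    keys <- names(hist$counts)
    acc <- new.env(parent = emptyenv())
    for (k in seq_along(keys)) {
      c_k <- hist$counts[[k]]
      bits <- as.integer(substring(keys[k], seq_len(n), seq_len(n)))
      out_idx <- numeric(c_k)
      for (q in seq_len(n)) {
        m <- calib$mats[[q]]
        p_flip <- if (bits[q] == 0L) m[2, 1] else m[1, 2]
        flipped <- stats::rbinom(c_k, 1L, p_flip)
        b <- if (bits[q] == 0L) flipped else 1L - flipped
        out_idx <- out_idx + b * 2^(q - 1L)
      }
      tab <- table(out_idx)
      for (j in seq_along(tab)) {
        lab <- basis_label(as.integer(names(tab)[j]), n)
        acc[[lab]] <- (if (is.null(acc[[lab]])) 0 else acc[[lab]]) + tab[[j]]
      }
    }
    vals <- unlist(as.list(acc))
    shot_histogram(vals, n)
  }
  if (is.null(seed)) run() else with_seed_local(seed, run())
}

#' Correct measured counts with a calibration (M3-style)
#'
#' Solves the tensor-product readout model `A p_true = p_measured`
#' restricted to the subspace spanned by the observed bitstrings and their
#' single-bit-flip neighbors, then renormalizes to total mass 1. Entries of
#' the solution may be slightly negative (quasi-probabilities); they are
#' reported as-is alongside a clipped-at-zero, renormalized variant.
#'
#' @param hist A [shot_histogram()].
#' @param calib A [readout_calibration()]; every per-qubit matrix must be
#'   invertible (a symmetric flip probability of 0.5 is singular and
#'   rejected).
#' @return An object of class `mitigated_counts` with `quasi` and `clipped`
#'   named probability vectors.
#' @export
mitigate <- function(hist, calib) {
  stopifnot(inherits(hist, "shot_histogram"),
            inherits(calib, "readout_calibration"))
  n <- hist$n_qubits
  if (n != calib$n_qubits) {
    stop("histogram and calibration register sizes differ", call. = FALSE)
  }
  for (m in calib$mats) {
    if (abs(det(m)) < 1e-10) {
      stop("calibration matrix is (near-)singular; readout cannot be ",
           "inverted", call. = FALSE)
    }
  }
  observed <- vapply(names(hist$counts), basis_index, numeric(1))
  neighbors <- unlist(lapply(observed, function(b) {
    vapply(0:(n - 1L), function(q) bitwXor(as.integer(b),
                                           bitwShiftL(1L, q)), numeric(1))
  }))
  sub <- sort(unique(c(observed, neighbors)))
  labs <- vapply(as.integer(sub), basis_label, character(1), n_qubits = n)
  bits <- key_bit_matrix(labs, n)
  d <- length(sub)
  M <- matrix(1, d, d)
  for (q in seq_len(n)) {
    A <- calib$mats[[q]]
    M <- M * matrix(A[cbind(rep(bits[, q] + 1L, d),
                            rep(bits[, q] + 1L, each = d))], d, d)
  }
  freq <- stats::setNames(numeric(d), labs)
  freq[names(hist$counts)] <- hist$counts / hist$shots
  x <- solve(M, freq)
  x <- x / sum(x)
  clipped <- pmax(x, 0)
  clipped <- clipped / sum(clipped)
  structure(list(n_qubits = n, shots = hist$shots,
                 quasi = stats::setNames(as.numeric(x), labs),
                 clipped = stats::setNames(as.numeric(clipped), labs)),
            class = "mitigated_counts")
}

#' @export
print.mitigated_counts <- function(x, ...) {
  cat("<mitigated_counts> ", x$n_qubits, " qubit(s), ",
      length(x$quasi), " bitstrings, min quasi-probability ",
      format(min(x$quasi), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Total-variation distance between two distributions over bitstrings
#'
#' @param p,q Named numeric vectors (bitstring -> probability/weight);
#'   missing keys count as 0.
#' @return `0.5 * sum(|p - q|)` over the union of keys.
#' @export
tv_distance <- function(p, q) {
  keys <- union(names(p), names(q))
  pv <- stats::setNames(numeric(length(keys)), keys)
  qv <- pv
  pv[names(p)] <- p
  qv[names(q)] <- q
  0.5 * sum(abs(pv - qv))
}

#' Exact outcome probabilities of a state
#'
#' @param state A [pure_state()].
#' @return Named numeric vector of `|amplitude|^2` over all bitstrings.
#' @export
state_probs <- function(state) {
  stopifnot(inherits(state, "pure_state"))
  p <- Mod(state$amplitudes)^2
  stats::setNames(p, vapply(0:(length(p) - 1L), basis_label, character(1),
                            n_qubits = state$n_qubits))
}

# --- JSON ------------------------------------------------------------------

#' Histogram JSON round-trip
#'
#' @param hist A [shot_histogram()].
#' @param path Optional file path.
#' @return JSON text (invisibly when writing).
#' @export
histogram_to_json <- function(hist, path = NULL) {
  stopifnot(inherits(hist, "shot_histogram"))
  obj <- list(n_qubits = hist$n_qubits, shots = hist$shots,
              counts = as.list(hist$counts))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname histogram_to_json
#' @param json JSON text or file path.
#' @export
histogram_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  shot_histogram(unlist(obj$counts), as.integer(obj$n_qubits))
}

#' Calibration JSON round-trip
#'
#' @param calib A [readout_calibration()].
#' @param path Optional file path.
#' @return JSON text (invisibly when writing).
#' @export
calibration_to_json <- function(calib, path = NULL) {
  stopifnot(inherits(calib, "readout_calibration"))
  obj <- list(n_qubits = calib$n_qubits,
              matrices = lapply(calib$mats, function(m) {
                list(as.numeric(m[, 1]), as.numeric(m[, 2]))
              }))
  txt <- jsonlite::toJSON(obj, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname calibration_to_json
#' @param json JSON text or file path.
#' @export
calibration_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  mats <- lapply(obj$matrices, function(cols) {
    cbind(vapply(cols[[1]], as.numeric, numeric(1)),
          vapply(cols[[2]], as.numeric, numeric(1)))
  })
  calibration_from_matrices(mats)
}
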