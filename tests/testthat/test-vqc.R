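test_that("build_layer emits a U3 column plus the CZ entangler", {
  frag8 <- build_layer(matrix(rnorm(24), 8, 3), 8)
  kinds <- vapply(frag8$ops, function(o) o$kind, character(1))
  expect_equal(sum(kinds == "U3"), 8)
  expect_equal(sum(kinds == "CZ"), 8)  # ring closes
  frag2 <- build_layer(matrix(0, 2, 3), 2)
  expect_equal(vapply(frag2$ops, function(o) o$kind, character(1)),
               c("U3", "U3", "CZ"))  # degenerate 2-qubit ring: single CZ
  frag1 <- build_layer(matrix(0, 1, 3), 1)
  expect_equal(vapply(frag1$ops, function(o) o$kind, character(1)), "U3")
  chain <- build_layer(matrix(0, 4, 3), 4, entangler = "chain")
  cz <- Filter(function(o) o$kind == "CZ", chain$ops)
  expect_equal(length(cz), 3)
  expect_equal(cz[[1]]$targets, c(0L, 1L))
})

test_that("vqc_forward matches its defining special cases", {
  # zero params + zero features: uniform probabilities survive the CZs
  p <- vqc_params(3, 2)
  expect_lt(max(abs(vqc_forward(p, angle_embed(c(0, 0, 0))))), 1e-12)
  # zero params on |0...0>: CZ acts trivially, all <Z> = +1
  expect_equal(vqc_forward(p, zero_state(3)), c(1, 1, 1))
  # zero-angle layers are diagonal, so any embedding's Z profile is kept
  set.seed(2)
  x <- rnorm(3)
  expect_lt(max(abs(vqc_forward(p, angle_embed(x)) + sin(atan(x)))), 1e-12)
  expect_error(vqc_forward(p, zero_state(2)), "qubits")
})

test_that("vqc_forward agrees with the dense matrix oracle", {
  set.seed(14)
  for (rep in 1:10) {
    p <- vqc_params(3, 2, array(runif(18, -pi, pi), c(2, 3, 3)))
    st <- random_state(3)
    want_amp <- oracle_run_circuit(variational_circuit(p), st)
    want <- as.numeric(vqchead:::z_sign_matrix(3) %*% Mod(want_amp)^2)
    expect_lt(max(abs(vqc_forward(p, st) - want)), 1e-9)
    expect_true(all(abs(vqc_forward(p, st)) <= 1 + 1e-12))
  }
})

test_that("parameter counting is 3KN and the FC comparison quadratic", {
  expect_identical(count_params(16, 2), 96L)
  expect_identical(count_params(8, 2), 48L)
  expect_identical(count_params(1, 1), 3L)
  for (n in c(2, 4, 8, 16)) {
    expect_equal(count_params(n, 2), 3 * 2 * n)   # linear in N
    expect_equal(middle_block_params(n, 2)$fc_weights, n^2)  # quadratic
  }
  mb <- middle_block_params(16, 2)
  expect_equal(1 - mb$vqc_params / mb$fc_weights, 0.625)
  expect_equal(middle_block_params(8, 2)$reduction_pct, 25)
})

test_that("parameter-shift gradients match finite differences and adjoint", {
  set.seed(77)
  for (rep in 1:8) {
    p <- vqc_params(3, 2, array(runif(18, -pi, pi), c(2, 3, 3)))
    st <- random_state(3)
    up <- rnorm(3)
    gs <- parameter_shift_grad(p, st, up)
    expect_lt(max(abs(gs - oracle_fd_grad(p, st, up))), 1e-5)
    expect_lt(max(abs(gs - vqc_grad_adjoint(p, st, up))), 1e-9)
    expect_lt(max(abs(gs - vqc_grad(p, st, up, method = "adjoint"))), 1e-9)
  }
})

test_that("zero upstream weights give a zero gradient", {
  set.seed(4)
  p <- vqc_params(2, 2, array(rnorm(12), c(2, 2, 3)))
  g <- parameter_shift_grad(p, random_state(2), c(0, 0))
  expect_equal(max(abs(g)), 0)
})

test_that("single-qubit theta gradient vanishes at the |0> stationary point", {
  # <Z> after U3(theta,0,0)|0> is cos(theta); derivative at 0 is 0
  p <- vqc_params(1, 1)
  g <- parameter_shift_grad(p, zero_state(1), 1)
  expect_equal(g[1, 1, 1], 0, tolerance = 1e-12)
})

test_that("parameters checkpoint to JSON and back", {
  set.seed(6)
  p <- vqc_params(4, 3, array(rnorm(36), c(3, 4, 3)), entangler = "chain")
  q <- vqc_params_from_json(vqc_params_to_json(p))
  expect_identical(q$n_qubits, p$n_qubits)
  expect_identical(q$n_layers, p$n_layers)
  expect_identical(q$entangler, p$entangler)
  expect_equal(q$angles, p$angles)
})

test_that("the exported QASM program has the documented structure", {
  p0 <- vqc_params(1, 1)
  qasm <- vqc_to_qasm(p0, 0)
  expect_match(qasm, "h q\\[0\\];")
  expect_match(qasm, "ry\\(0\\) q\\[0\\];")
  # N = 8, K = 2: 8 H + 16 embedding rotations + 2 * (8 U3 + 8 CZ)
  set.seed(3)
  p8 <- vqc_params(8, 2, array(rnorm(48), c(2, 8, 3)))
  x8 <- rnorm(8)
  prog <- vqc_to_qasm(p8, x8)
  instr <- strsplit(prog, "\n")[[1]]
  instr <- instr[grepl("^(h|ry|rz|u3|cz)", instr)]
  expect_length(instr, 56)
  # round trip preserves gates and angles
  circ <- circuit_from_qasm(prog)
  ref <- circuit_spec(8, c(angle_embedding_circuit(x8)$ops,
                           variational_circuit(p8)$ops))
  for (i in seq_along(ref$ops)) {
    expect_identical(circ$ops[[i]]$kind, ref$ops[[i]]$kind)
    expect_equal(circ$ops[[i]]$angles, ref$ops[[i]]$angles,
                 tolerance = 1e-12)
  }
  # and the reimported program drives the simulator to the same state
  got <- run_circuit(circ)
  want <- run_circuit(ref)
  expect_lt(max(Mod(got$amplitudes - want$amplitudes)), 1e-9)
})

test_that("fast head kernel agrees with the gate-object circuit route", {
  set.seed(19)
  for (rep in 1:5) {
    n <- sample(2:5, 1)
    K <- sample(1:3, 1)
    z <- rnorm(n)
    p <- vqc_params(n, K, array(runif(3 * K * n, -pi, pi), c(K, n, 3)))
    kern <- vqchead:::head_kernel(n, "ring")
    fast <- vqchead:::vqc_fast_forward(kern, atan(z), p$angles)
    ref <- vqc_forward(p, angle_embed(z))
    expect_lt(max(abs(fast$m - ref)), 1e-12)
    up <- rnorm(n)
    bw <- vqchead:::vqc_fast_backward(kern, atan(z), p$angles, fast$amp, up)
    expect_lt(max(abs(bw$gvqc - vqc_grad_adjoint(p, angle_embed(z), up))),
              1e-10)
  }
})
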