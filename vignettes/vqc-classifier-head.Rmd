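---
title: "The simulated VQC classifier head: model, training protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The simulated VQC classifier head}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vqchead)
```

## The model

`vqchead` simulates a hybrid quantum–classical classification head. A
classical feature vector `x` (standing in for the penultimate activations
of a vision backbone) passes through a linear map to `N` middle features
`z`, which are encoded into an `N`-qubit state, transformed by `K`
trainable circuit layers, read out as per-qubit Pauli-Z expectations, and
mapped linearly to two logits. The classical comparator is identical
except that the quantum middle block is an `N x N` linear layer.

**State and gates.** States are dense complex vectors of length `2^N`
(capped at 24 qubits, a 128 MiB vector, to fail fast on accidental large
registers). The gate set is `H`, `RY`, `RZ`, `U3`, `CZ` — the native gate
set of current superconducting processors, so exported OpenQASM programs
need no decomposition. Rotation conventions are the OpenQASM ones:
`RY(t) = exp(-i t Y / 2)`, `RZ(t) = exp(-i t Z / 2)`, and
`U3(theta, phi, lambda) = RZ(phi) RY(theta) RZ(lambda)` up to a global
phase. Qubit 0 is the least-significant bit of the basis index
(little-endian), used consistently by sampling, expectation and bitstring
code. `apply_gate` returns a fresh state; referential transparency keeps
gradient checking simple. Global phase is physically meaningless, so
cross-toolkit comparisons (and our own U3-vs-decomposition tests) compare
states only up to a phase factor.

**Angle embedding.** Each middle feature is squashed by `arctan` into
`(-pi/2, pi/2)` and written onto its own qubit as `H`, then `RY(x')`,
then `RZ((x')^2)`. The squared-angle RZ adds representational capacity
but provably cannot change the Z profile of a product state, so the
embedding's readout has the closed form `<Z_i> = -sin(arctan z_i)` — a
smooth, bounded squashing that behaves like a `tanh` nonlinearity and is
used as an exact oracle in the tests. The amplitude embedding
(L2-normalized features written directly into amplitudes, zero-padded to
the next power of two, `ceil(log2 N)` qubits) is implemented by direct
assignment: the state-preparation circuit it would need on hardware has
`O(N)` depth, which is exactly why it is treated as simulator-only. Basis
embedding is included for completeness; continuous features make it
unsuitable as a head encoding. Zero-padding happens after normalization —
the pads are zeros either way, so the two orders coincide.

**Variational block.** Each layer is a column of per-qubit `U3` rotations
followed by a CZ entangler. The entangler is a ring (`i` with
`i+1 mod N`) by default, following the strongly entangling circuit-centric
classifier architecture this design descends from; a `chain` option (no
wrap-around) matches linear hardware topologies, since published chip
layouts suggest nearest-neighbour pairs and the choice is otherwise open.
For `N = 2` the ring degenerates to a single CZ; for `N = 1` there is no
entangler. Layers are applied first-to-last; because the layers are
architecturally identical, the opposite reading of the layer product
merely relabels parameters. With all angles zero every layer is diagonal,
so the head's readout reduces exactly to the embedding's Z profile — the
degenerate-case anchor the tests use.

**Readout.** The per-qubit expectation vector, not the single `Z^{⊗N}`
parity scalar, is the head's output: the downstream linear layer needs an
N-vector, and the parity scalar would discard almost all of the state's
information. This is the one place where the two natural readings of the
measurement step disagree, and the vector reading is the one consistent
with the head dimensions.

## Gradients

Two exact routes are implemented and cross-checked:

* **Adjoint backpropagation** (default in simulation): one forward pass,
  one backward sweep that un-applies each gate and accumulates
  `2 Re(<lambda| dG |psi>)` per angle. Cost is linear in circuit size; the
  inner loop works from four subspace inner products per gate, so the
  per-sample gradient at `N = 8, K = 2` costs about two forward passes.
* **Parameter shift** (the hardware-compatible route): each `U3` is
  rewritten as `RZ(phi) RY(theta) RZ(lambda)` — exact up to global phase —
  so every angle sits in a plain rotation gate and obeys the two-point
  rule `df/da = (f(a + pi/2) - f(a - pi/2)) / 2`.

The suite requires the two routes to agree with central finite
differences to 1e-5 and with each other to 1e-9; the fast fused kernel
used in training is additionally pinned to the generic gate-object
implementation to 1e-12.

## Training protocol

The reference protocol is SGD with momentum 0.9 and weight decay 1e-4,
label-smoothed cross-entropy, cosine annealing to zero over 80 epochs with
no restarts, a class-balanced resampling loader, and two learning-rate
groups: 0.0004 for the classical linear maps, 0.004 for the quantum
angles. The 10x quantum rate compensates for the circuit's bounded
`[-1, 1]` output range. Decisions where the protocol was underspecified:

* **Label smoothing 0.1** — the common default; configurable.
* **Weight decay on the classical group only** — rotation angles are
  periodic, so shrinking them toward zero has no regularizing meaning.
  Classical biases are decayed with their weights for simplicity.
* **Oversampling** with replacement (class picked fairly, member uniform)
  rather than undersampling, so no data is discarded; the validation loss
  is computed with the plain loader, since evaluation should reflect the
  data as it is.
* **Per-sample updates** (batch size 1): with n of a few hundred and a
  head this small, minibatching buys nothing and single-sample SGD keeps
  the update rule transparent.
* **Analytic expectations during training**; finite shots are an
  inference-time option for parity with hardware runs (1000 shots being
  the reference setting). Training on shot estimates would need the
  parameter-shift route and is out of scope of the protocol.
* **Initialization**: linear maps `N(0, 1/fan_in)`, biases zero, angles
  `N(0, 0.1)` so the circuit starts near the identity and the initial
  middle block behaves like the smooth embedding squashing.
* **NaN losses abort** with a diagnostic rather than silently continuing.

All randomness (initialization, loader, shot draws) flows from the
training seed; two runs with identical configs and seeds are
bit-identical in analytic mode, which the suite asserts.

## Measurement and readout mitigation

`sample_shots` draws a seeded multinomial from `|amplitude|^2`.
Readout noise is modelled as independent per-qubit 2x2 column-stochastic
confusion matrices — a tensor-product model. Real calibration-based
mitigation (M3) also handles correlated readout, but with no correlation
data to calibrate against, the product model is the testable stand-in;
the implementation is therefore called *M3-style*. Correction solves the
confusion system restricted to the observed bitstrings and their
single-bit-flip neighbours, mirroring the matrix-free motivation: cost
stays `O(shots * n)` instead of `O(4^n)`. The restricted solve can lose a
sliver of probability mass, so the solution is renormalized to total mass
1 (the suite checks 1e-6). Quasi-probabilities are reported unclipped by
default — negative entries are information about noise inversion — with a
clipped-and-renormalized variant alongside; expectation code accepts
either. A symmetric flip probability of 0.5 makes the confusion matrix
singular and is rejected with a conditioning error.

## Synthetic data: what it does and does not show

The generator emulates two-class penultimate-feature distributions with a
controllable Mahalanobis separation: unit-covariance Gaussian blobs
`separation` apart along the first axis, or a ring-vs-disc pair for a
nonlinearly separable variant; optional label noise flips a stated
fraction. Splits are independent seeded draws, hence disjoint by
construction, and a dataset is a pure function of its spec (`same seed,
same CSV bytes`).

Real backbone features are none of these things: they are correlated,
non-Gaussian, and their class structure is not axis-aligned. Passing
tests on this generator therefore demonstrates that the head, gradients
and protocol are *implemented correctly and can learn a learnable task* —
not that the VQC head matches or beats an FC head on clinical data. For
the same reason the VQC-vs-FC harness treats the overfitting-gap
comparison as a protocol whose outputs are reported, not asserted: on
arbitrary synthetic data, "the VQC gap is smaller" is a scientific
hypothesis, while the implementation contracts (computability,
determinism, parameter counts `3KN` vs `N^2`) are what the tests pin
down.

## Numerical choices and problem sizes

* Norm and unitarity tolerances: states stay normalized to 1e-9 across
  any gate sequence; every gate matrix is unitary to 1e-12.
* Oracle checks run the dense Kronecker-product construction at
  `N <= 4` (200 random circuits), where the full matrix is cheap and
  obviously correct.
* Finite-difference gradient checks use central differences with
  `h = 1e-5` at `N = 4, K = 2` over 50 random instances, tolerance 1e-5.
* The shot-convergence bound `3/sqrt(shots)` is the 3-sigma envelope for
  a variance-1 observable; at the reference 1000 shots the suite demands
  coverage of at least 99 % over 1000 seeded trials.
* The training-scale demonstration uses `n = 400` per split, `N = 8`
  qubits, separation 6, 80 epochs — large enough for the protocol to be
  exercised end-to-end, small enough to rerun routinely; the scaled-down
  comparison in the unit tests uses `n = 60` and 3 epochs, checking
  protocol mechanics rather than learning outcomes.
* AUC is the trapezoid integral of the full threshold sweep and is
  required to equal the pairwise Mann-Whitney statistic (ties at 1/2)
  to 1e-12; BACC must equal the mean of sensitivity and specificity to
  1e-12 on every report. Degenerate inputs (a missing class) raise
  explicit undefined-metric errors rather than returning NaN.

## Known limitations

* Pure states only: no density matrices, decoherence channels or
  mid-circuit measurement; noise enters solely at readout.
* No hardware transpilation or SWAP routing — the gate set and the
  ring/chain entangler are chosen so none is needed.
* Amplitude-embedding training gradients are not implemented (the head
  trains with the angle embedding, which is also the hardware-practical
  choice); amplitude embedding is available for forward evaluation and
  comparison.
* The classifier is strictly binary, matching the screening task the
  head design targets.
* Statevector cost is `O(2^N)` per gate: 16 qubits is comfortable, 24 is
  the hard cap.
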