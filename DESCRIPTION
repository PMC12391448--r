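Package: vqchead
Title: Variational Quantum Circuit Classifier Heads, Simulated and Differentiable
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Exact statevector simulation of the variational quantum circuit
    (VQC) classifier head used in hybrid quantum-classical transfer learning:
    angle, amplitude and basis embeddings of classical feature vectors,
    strongly entangling layers of U3 rotations with a controlled-Z
    entanglement ring, analytic (adjoint) and parameter-shift gradients,
    shot-based Pauli-Z measurement with seeded multinomial sampling, and
    tensor-product readout-error mitigation. Includes the full hybrid head
    (linear map, embedding, VQC, linear map) with a matched classical
    fully connected head, a joint SGD training protocol with per-group
    learning rates and cosine annealing, balanced resampling for imbalanced
    labels, binary classification metrics (balanced accuracy, sensitivity,
    specificity, ROC/AUC), a seeded synthetic two-class feature generator,
    and a VQC-versus-FC comparison harness reporting parameter counts and
    train/validation overfitting gaps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
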