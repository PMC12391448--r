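zero_weights <- function(cfg) {
  w <- init_head_weights(cfg)
  w$W_in[] <- 0; w$b_in[] <- 0; w$W_out[] <- 0; w$b_out[] <- 0
  if (cfg$head_kind == "vqc") w$vqc$angles[] <- 0
  else { w$W_mid[] <- 0; w$b_mid[] <- 0 }
  w
}

test_that("head_forward cascades identities as expected", {
  cfg <- head_config(4, n_qubits = 4, head_kind = "vqc")
  w <- zero_weights(cfg)
  w$b_out <- c(0.3, -0.2)
  set.seed(1)
  fw <- head_forward(cfg, w, rnorm(4))
  expect_lt(max(abs(fw$middle)), 1e-12)  # zero middle input, zero angles
  expect_equal(fw$logits, c(0.3, -0.2))
  # fc head: identity maps pass the first two coordinates through
  cfg2 <- head_config(4, n_qubits = 4, head_kind = "fc")
  w2 <- zero_weights(cfg2)
  w2$W_in <- diag(4); w2$W_mid <- diag(4)
  w2$W_out <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  fw2 <- head_forward(cfg2, w2, c(0.7, -0.4, 9, 9))
  expect_equal(fw2$logits, c(0.7, -0.4))
  expect_error(head_forward(cfg, w, rnorm(5)), "expected 4 features")
})

test_that("shot-mode readout converges to the analytic expectations", {
  cfg <- head_config(3, n_qubits = 3, head_kind = "vqc")
  set.seed(10)
  w <- init_head_weights(cfg)
  x <- rnorm(3)
  exact <- head_forward(cfg, w, x, shots = 0)$middle
  sampled <- head_forward(cfg, w, x, shots = 100000, seed = 123)$middle
  expect_lt(max(abs(sampled - exact)), 3 / sqrt(100000))
})

test_that("label-smoothed cross-entropy matches its closed forms", {
  expect_equal(head_loss(c(0, 0), 0, 0), log(2))
  expect_equal(head_loss(c(0, 0), 1, 0), log(2))
  expect_equal(head_loss(c(0, 0), 1, 0.1), log(2))  # smoothing-invariant here
  expect_lt(head_loss(c(-40, 40), 1, 0), 1e-12)     # confident and correct
  expect_gt(head_loss(c(40, -40), 1, 0), 50)        # confident and wrong
  # hand-computed smoothed case
  lp <- c(0.25, -0.25) - log(sum(exp(c(0.25, -0.25) - 0.25))) - 0.25
  expect_equal(head_loss(c(0.25, -0.25), 1, 0.2),
               -(0.1 * lp[1] + 0.9 * lp[2]))
})

test_that("one small SGD step decreases the sample loss", {
  set.seed(55)
  for (rep in 1:20) {
    kind <- if (rep %% 2 == 0) "vqc" else "fc"
    cfg <- head_config(5, n_qubits = 4, head_kind = kind)
    w <- init_head_weights(cfg)
    x <- rnorm(5); lab <- rbinom(1, 1, 0.5)
    hg <- vqchead:::head_grad(cfg, w, x, lab, 0.1)
    lr <- 1e-4
    w2 <- w
    for (nm in names(w2)) {
      if (nm == "vqc") w2$vqc$angles <- w2$vqc$angles - lr * hg$grads$vqc
      else w2[[nm]] <- w2[[nm]] - lr * hg$grads[[nm]]
    }
    l2 <- head_loss(head_forward(cfg, w2, x)$logits, lab, 0.1)
    expect_lt(l2, hg$loss)
  }
})

test_that("learning-rate groups route updates to the right parameters", {
  cfg <- head_config(3, n_qubits = 3, head_kind = "vqc")
  set.seed(2)
  w <- init_head_weights(cfg)
  g <- list(W_in = matrix(1, 3, 3), b_in = rep(1, 3),
            W_out = matrix(1, 2, 3), b_out = rep(1, 2),
            vqc = array(1, c(2, 3, 3)))
  tc <- train_config(momentum = 0, weight_decay = 0)
  u <- vqchead:::sgd_update(w, g, vqchead:::zero_like_weights(w), tc,
                            lr_c = 1e-3, lr_q = 1e-2)
  expect_equal(u$weights$W_in, w$W_in - 1e-3)       # classical rate
  expect_equal(u$weights$vqc$angles, w$vqc$angles - 1e-2)  # quantum rate
  # weight decay touches classical weights only
  tc2 <- train_config(momentum = 0, weight_decay = 0.5)
  g0 <- vqchead:::zero_like_weights(w)
  u2 <- vqchead:::sgd_update(w, g0, vqchead:::zero_like_weights(w), tc2,
                             lr_c = 1, lr_q = 1)
  expect_equal(u2$weights$W_out, w$W_out * 0.5)
  expect_equal(u2$weights$vqc$angles, w$vqc$angles)  # angles not decayed
})

test_that("cosine annealing halves the rate mid-run and anneals to zero", {
  expect_equal(cosine_lr(0, 80, 4e-4), 4e-4)
  expect_equal(cosine_lr(40, 80, 4e-4), 2e-4)
  expect_lt(cosine_lr(79, 80, 4e-4), 4e-4 * 0.001)
  tc <- train_config()
  expect_equal(tc$lr_quantum / tc$lr_classical, 10)
})

test_that("balanced resampling equalizes expected class frequencies", {
  y <- c(rep(0L, 900), rep(1L, 100))
  idx <- balanced_sample_indices(y, 1000, seed = 7)
  n1 <- sum(y[idx] == 1)
  sigma <- sqrt(1000 * 0.25)
  expect_lt(abs(n1 - 500), 3 * sigma)
  # already balanced data stays balanced
  yb <- rep(c(0L, 1L), 500)
  idxb <- balanced_sample_indices(yb, 1000, seed = 8)
  expect_lt(abs(sum(yb[idxb] == 1) - 500), 3 * sigma)
  # determinism and failure on a single class
  expect_identical(balanced_sample_indices(y, 200, seed = 3),
                   balanced_sample_indices(y, 200, seed = 3))
  expect_error(balanced_sample_indices(rep(1L, 10), 5), "both classes")
})

small_problem <- function() {
  spec <- synthetic_spec(n_train = 40, n_val = 40, n_features = 4,
                         separation = 3, seed = 1)
  list(train = generate_dataset(spec, "train"),
       val = generate_dataset(spec, "val"))
}

test_that("training is bit-reproducible under a fixed seed", {
  d <- small_problem()
  cfg <- head_config(4, n_qubits = 4, head_kind = "vqc")
  tc <- train_config(epochs = 2, seed = 9)
  f1 <- train_head(d$train, cfg, tc, val_data = d$val)
  f2 <- train_head(d$train, cfg, tc, val_data = d$val)
  expect_identical(f1$curves, f2$curves)
  expect_identical(f1$weights$vqc$angles, f2$weights$vqc$angles)
  f3 <- train_head(d$train, cfg, train_config(epochs = 2, seed = 10),
                   val_data = d$val)
  expect_false(identical(f1$curves$train_loss, f3$curves$train_loss))
})

test_that("zero learning rates leave parameters and curves flat", {
  d <- small_problem()
  cfg <- head_config(4, n_qubits = 4, head_kind = "fc")
  tc <- train_config(epochs = 3, lr_classical = 0, lr_quantum = 0,
                     balanced_resampling = FALSE, seed = 0)
  fit <- train_head(d$train, cfg, tc, val_data = d$val)
  set.seed(0)
  w0 <- init_head_weights(cfg)
  expect_equal(fit$weights$W_mid, w0$W_mid)
  expect_equal(diff(range(fit$curves$train_loss)), 0, tolerance = 1e-12)
  expect_equal(diff(range(fit$curves$val_loss)), 0, tolerance = 1e-12)
})

test_that("tidy, glance, predict and overfit_gap expose the fit", {
  d <- small_problem()
  cfg <- head_config(4, n_qubits = 4, head_kind = "vqc")
  fit <- train_head(d$train, cfg, train_config(epochs = 2, seed = 0),
                    val_data = d$val)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_named(td, c("epoch", "train_loss", "val_loss", "lr_classical",
                     "lr_quantum"))
  gl <- glance(fit)
  expect_equal(gl$middle_params, count_params(4, 2))
  expect_equal(gl$overfit_gap, gl$val_loss - gl$train_loss)
  pr <- predict(fit, d$val)
  expect_equal(nrow(pr), 40)
  expect_true(all(pr$.pred_prob >= 0 & pr$.pred_prob <= 1))
  expect_equal(pr$.pred_class, as.integer(pr$.pred_prob >= 0.5))
  og <- overfit_gap(fit)
  expect_equal(nrow(og$series), 2)
  expect_equal(og$gap, gl$overfit_gap)
  # identical curves give zero gap; a constant offset is returned exactly
  cv <- tibble::tibble(epoch = 1:3, train_loss = c(1, 0.5, 0.4),
                       val_loss = c(1, 0.5, 0.4))
  expect_equal(overfit_gap(cv)$gap, 0)
  cv$val_loss <- cv$train_loss + 0.135
  expect_equal(overfit_gap(cv)$gap, 0.135)
  expect_true(all(is.finite(overfit_gap(cv)$series$gap)))
})

test_that("trained heads round-trip through JSON checkpoints", {
  d <- small_problem()
  for (kind in c("vqc", "fc")) {
    cfg <- head_config(4, n_qubits = 4, head_kind = kind)
    fit <- train_head(d$train, cfg, train_config(epochs = 1, seed = 0),
                      val_data = d$val)
    tf <- tempfile(fileext = ".json")
    save_head(fit, tf)
    back <- load_head(tf)
    expect_equal(predict(back, d$val)$.pred_prob,
                 predict(fit, d$val)$.pred_prob, tolerance = 1e-12)
    expect_equal(back$curves$train_loss, fit$curves$train_loss)
  }
})
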