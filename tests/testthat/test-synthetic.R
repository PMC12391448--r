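test_that("the generator is a deterministic function of its spec", {
  spec <- synthetic_spec(n_train = 50, n_val = 30, n_test = 20,
                         n_features = 5, seed = 42)
  a <- generate_dataset(spec, "train")
  b <- generate_dataset(spec, "train")
  expect_identical(a, b)
  expect_equal(dim(a), c(50, 6))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_dataset_csv(a, f1); write_dataset_csv(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # splits differ from each other
  expect_false(identical(a$f1[1:20], generate_dataset(spec, "val")$f1[1:20]))
  # different seeds differ
  spec2 <- synthetic_spec(n_train = 50, n_features = 5, seed = 43)
  expect_false(identical(a$f1, generate_dataset(spec2, "train")$f1))
})

test_that("separated blobs are nearly separable by the first feature", {
  spec <- synthetic_spec(n_train = 500, n_features = 4, separation = 6,
                         seed = 3)
  d <- generate_dataset(spec, "train")
  pred <- as.integer(d$f1 > 3)
  cm <- classification_metrics(confusion_counts(d$label, pred))
  expect_gte(cm$bacc, 0.95)
})

test_that("zero separation gives chance-level AUC", {
  spec <- synthetic_spec(n_train = 400, n_features = 4, separation = 0,
                         seed = 5)
  d <- generate_dataset(spec, "train")
  auc <- roc_auc(d$label, d$f1)$auc
  n1 <- sum(d$label == 1); n0 <- sum(d$label == 0)
  # Mann-Whitney null sd of AUC
  sd_null <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(auc - 0.5), 3 * sd_null)
})

test_that("label noise flips about the requested fraction", {
  spec <- synthetic_spec(n_train = 2000, n_features = 2, separation = 50,
                         label_noise = 0.2, seed = 7)
  d <- generate_dataset(spec, "train")
  # with huge separation the true class is read off f1; flips are visible
  true_class <- as.integer(d$f1 > 25)
  flip_rate <- mean(true_class != d$label)
  expect_lt(abs(flip_rate - 0.2), 3 * sqrt(0.2 * 0.8 / 2000))
})

test_that("ring_vs_disc places class 1 on the ring", {
  spec <- synthetic_spec(n_train = 600, n_features = 4, separation = 8,
                         noise_kind = "ring_vs_disc", seed = 2)
  d <- generate_dataset(spec, "train")
  r <- sqrt(d$f1^2 + d$f2^2)
  expect_gt(mean(r[d$label == 1]), 6)
  expect_lt(mean(r[d$label == 0]), 3)
  # not linearly separable along any single axis, but radially separable
  expect_gte(roc_auc(d$label, r)$auc, 0.95)
  expect_lt(roc_auc(d$label, d$f1)$auc, 0.7)
})

test_that("spec validation rejects degenerate settings", {
  expect_error(synthetic_spec(separation = -1), "nonnegative")
  expect_error(synthetic_spec(class_balance = 1), "class_balance")
  expect_error(synthetic_spec(label_noise = 0.5), "label_noise")
})

test_that("confusion counts partition the sample", {
  cc <- confusion_counts(c(1, 0, 1, 0), c(1, 1, 0, 0))
  expect_equal(unlist(cc), c(tp = 1, tn = 1, fp = 1, fn = 1))
  perfect <- confusion_counts(c(1, 1, 0), c(1, 1, 0))
  expect_equal(perfect$fp + perfect$fn, 0)
  allpos <- confusion_counts(rep(c(1, 0), 50), rep(1, 100))
  expect_equal(unlist(allpos), c(tp = 50, tn = 0, fp = 50, fn = 0))
  expect_error(confusion_counts(c(1, 2), c(0, 1)), "binary")
  expect_error(confusion_counts(c(1, 0), c(1)), "equal length")
})

test_that("sensitivity, specificity and BACC follow their formulas", {
  m <- classification_metrics(90, 80, 20, 10)
  expect_equal(unlist(m), c(sensitivity = 0.9, specificity = 0.8,
                            bacc = 0.85))
  expect_equal(classification_metrics(50, 0, 100, 0)$bacc, 0.5)
  expect_equal(unlist(classification_metrics(50, 50, 0, 0)),
               c(sensitivity = 1, specificity = 1, bacc = 1))
  expect_error(classification_metrics(0, 5, 5, 0), "no positive")
  expect_error(classification_metrics(5, 0, 0, 5), "no negative")
})

test_that("ROC sweeps thresholds monotonically and AUC handles ties", {
  r <- roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(r$auc, 1)
  expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[1], 0)
  expect_equal(r$roc$fpr[nrow(r$roc)], 1)
  expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  expect_true(all(diff(r$roc$fpr) >= 0))
  expect_true(all(diff(r$roc$tpr) >= 0))
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.3, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.1, 0.2)), "both classes")
})

test_that("trapezoid AUC equals the pairwise Mann-Whitney statistic", {
  set.seed(50)
  for (rep in 1:10) {
    n <- sample(c(20, 100, 200), 1)
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) %in% c(0, n)) labels[1:2] <- c(0, 1)
    scores <- round(rnorm(n), sample(c(1, 2, 8), 1))  # induce ties sometimes
    got <- roc_auc(labels, scores)
    expect_equal(got$auc, oracle_auc_mann_whitney(labels, scores),
                 tolerance = 1e-12)
    expect_true(all(diff(got$roc$fpr) >= 0) && all(diff(got$roc$tpr) >= 0))
    expect_gte(got$auc, 0); expect_lte(got$auc, 1)
  }
})

test_that("AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(52)
  labels <- rbinom(150, 1, 0.5)
  labels[1:2] <- c(0, 1)
  scores <- round(rnorm(150), 2)
  ours <- roc_auc(labels, scores)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c(0, 1),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("metrics_report ties the pieces together", {
  set.seed(51)
  labels <- rbinom(60, 1, 0.5)
  labels[1:2] <- c(0, 1)
  scores <- runif(60)
  rep <- metrics_report(labels, scores)
  expect_equal(rep$summary$bacc,
               (rep$summary$sensitivity + rep$summary$specificity) / 2,
               tolerance = 1e-12)
  expect_equal(rep$counts$tp + rep$counts$tn + rep$counts$fp + rep$counts$fn,
               60)
  g <- glance(rep)
  expect_named(g, c("tp", "tn", "fp", "fn", "sensitivity", "specificity",
                    "bacc", "auc"))
})
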