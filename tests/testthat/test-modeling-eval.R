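# Training, cross-validation, and validation metrics

test_that("auroc matches its definition and tie convention", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.5, 0.5, 0.5, 0.5), c(1, 1, 0, 0)), 0.5)
  expect_equal(auroc(c(0.2, 0.3, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_error(auroc(c(1, 2), c(1, 1)), "both classes")
  expect_error(auroc(1:3, c(1, 0)), "length")

  # O(n^2) pairwise enumeration oracle
  withr::with_seed(40, {
    for (trial in 1:10) {
      n <- 50
      y <- rbinom(n, 1, 0.4)
      if (length(unique(y)) < 2) next
      s <- round(rnorm(n), 1)               # ties likely
      pos <- s[y == 1]; neg <- s[y == 0]
      pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
      expect_equal(auroc(s, y), mean(pairs))
    }
  })
})

test_that("auroc agrees with an established ROC implementation", {
  withr::with_seed(43, {
    for (trial in 1:5) {
      y <- rbinom(80, 1, 0.5)
      if (length(unique(y)) < 2) next
      s <- rnorm(80) + y
      ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                            direction = "<", levels = c(0, 1))))
      expect_equal(auroc(s, y), ref)
    }
  })
})

test_that("auroc is invariant under strictly monotone score transforms", {
  withr::with_seed(41, {
    s <- rnorm(80)
    y <- rbinom(80, 1, 0.5)
    a0 <- auroc(s, y)
    expect_equal(auroc(exp(s), y), a0)
    expect_equal(auroc(plogis(3 * s + 2), y), a0)
  })
})

test_that("confusion metrics satisfy the report identities", {
  cm <- confusion_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(cm$accuracy, 1)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 1)

  # predict all-negative on 3 positives / 7 negatives
  cm2 <- confusion_metrics(rep(0, 10), c(rep(1, 3), rep(0, 7)))
  expect_equal(cm2$accuracy, 0.7)
  expect_equal(cm2$sensitivity, 0)
  expect_equal(cm2$specificity, 1)

  withr::with_seed(42, {
    p <- rbinom(30, 1, 0.5); t <- rbinom(30, 1, 0.5)
    cm3 <- confusion_metrics(p, t)
    expect_equal(cm3$tp, sum(p == 1 & t == 1))
    expect_equal(cm3$tp + cm3$fp + cm3$tn + cm3$fn, 30)
    expect_equal(cm3$sensitivity, cm3$tp / (cm3$tp + cm3$fn))
    expect_equal(cm3$specificity, cm3$tn / (cm3$tn + cm3$fp))
  })
  expect_error(confusion_metrics(c(1, 0), c(1, 0, 1)), "length")
})

test_that("all four families separate a cleanly separable matrix", {
  withr::with_seed(50, {
    n <- 60
    X <- cbind(a = c(rnorm(n / 2, 4, 0.5), rnorm(n / 2, -4, 0.5)),
               b = rnorm(n))
    fm <- make_matrix(X, rep(c("arrest", "control"), each = n / 2))
  })
  for (fam in c("linear", "tree", "neural_net", "svm")) {
    m <- train_model(fm, fam, cv_folds = 5, seed = 3)
    expect_equal(m$cv_mean, 1, label = fam)
    expect_equal(m$train_accuracy, 1, label = fam)
  }
})

test_that("training is deterministic under a fixed seed", {
  fm <- make_signal_matrix(n_per_class = 25, p = 10, seed = 9)
  for (fam in c("linear", "tree", "neural_net", "svm")) {
    m1 <- train_model(fm, fam, cv_folds = 4, seed = 5)
    m2 <- train_model(fm, fam, cv_folds = 4, seed = 5)
    expect_identical(c(m1$cv_mean, m1$cv_sd), c(m2$cv_mean, m2$cv_sd),
                     label = fam)
    expect_identical(predict(m1, fm), predict(m2, fm), label = fam)
  }
})

test_that("cv folds with a single class are rejected and holdout is refused", {
  fm <- make_matrix(matrix(rnorm(12), 6),
                    c(rep("arrest", 2), rep("control", 4)))
  expect_error(train_model(fm, "linear", cv_folds = 4, seed = 1),
               "single class")
  big <- make_signal_matrix(n_per_class = 20, p = 5, seed = 3)
  p <- partition_holdout(big, 0.3, seed = 1)
  expect_error(train_model(p$holdout, "linear", cv_folds = 2), "holdout")
})

test_that("permuted labels give chance-level holdout discrimination", {
  aucs <- vapply(1:20, function(s) {
    withr::with_seed(600 + s, {
      X <- matrix(rnorm(200 * 8), 200)
      labels <- sample(rep(c("arrest", "control"), each = 100))
      fm <- make_matrix(X, labels)
      p <- partition_holdout(fm, 0.33, seed = s)
      m <- train_model(p$train, "linear", cv_folds = 0, seed = s)
      evaluate_model(m, p$holdout)$auroc
    })
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.07)
})

test_that("the factorial comparison emits one report per cell", {
  fc <- feature_config(continuous = c("hr", "spo2", "sbp", "dbp"),
                       latents = "si")
  co <- simulate_cohort(cohort_config(12, 12, seed = 2))
  fm <- quiet_matrix(co, fc)
  # a small network keeps the wide no-reduction cells cheap; the grid shape
  # under test is unaffected
  res <- compare_subsets(fm, target_k = 5, cv_folds = 2, seed = 1,
                         hyper = list(hidden = 2, maxit = 50))
  expect_equal(nrow(res), 5 * 3 * 4)
  expect_equal(nrow(unique(res[, c("subset", "selector", "family")])), 60)
  expect_true(all(res$auroc >= 0 & res$auroc <= 1))
  expect_true(all(res$tp + res$fp + res$tn + res$fn == nrow(fm) -
                    nrow(partition_holdout(fm, 0.33, 1)$train)))
  expect_true(all(res$balanced_design))
  # NONE cells report the overfitting gap
  expect_true(all(is.finite(res$overfit_gap[res$selector == "NONE"])))
})
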