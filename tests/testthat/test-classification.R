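# NNLS sparse-representation classifier and its robustness harness.

test_that("missing-aware gram restricts to common support and normalizes", {
  expect_equal(missing_aware_gram(matrix(c(1, 2, NaN)),
                                  matrix(c(NaN, 1, 1)))[1, 1], 1)
  expect_equal(missing_aware_gram(matrix(c(3, 4, NaN, NaN)),
                                  matrix(c(3, 4, 1, NaN)))[1, 1], 1)
  # complete pre-normalized columns reduce to the plain Gram matrix
  set.seed(70)
  X <- matrix(rnorm(40), 8, 5)
  X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  expect_equal(missing_aware_gram(X, X), crossprod(X), tolerance = 1e-12,
               ignore_attr = TRUE)
  # disjoint support is an explicit error
  expect_error(missing_aware_gram(matrix(c(1, NaN)), matrix(c(NaN, 1))),
               "disjoint")
})

test_that("missing-aware gram is invariant to global positive scaling", {
  set.seed(71)
  X <- matrix(rnorm(60), 10, 6)
  X[sample(60, 12)] <- NaN
  expect_equal(missing_aware_gram(X, X), missing_aware_gram(3 * X, 3 * X),
               tolerance = 1e-12)
})

test_that("change_class_labels remaps to 0..C-1", {
  m <- change_class_labels(c("B", "A", "B", "C"))
  expect_equal(m$y, c(1L, 0L, 1L, 2L))
  expect_equal(m$levels, c("A", "B", "C"))
  expect_error(change_class_labels(rep("A", 3)), "two classes")
})

test_that("nnls_fit stores the training gram; rbf entries lie in (0, 1]", {
  set.seed(72)
  X <- matrix(runif(24), 6, 4)
  m <- nnls_fit(X, c(0, 0, 1, 1))
  expect_equal(dim(m$gram), c(4L, 4L))
  expect_equal(m$gram, t(m$gram))
  mr <- nnls_fit(X, c("a", "a", "b", "b"), spec = kernel_spec("rbf",
                                                              sigma = 1))
  expect_true(all(mr$gram > 0 & mr$gram <= 1 + 1e-12))
  expect_error(nnls_fit(X, rep(1, 4)), "two classes")
})

test_that("an unknown equal to a training sample is self-represented", {
  set.seed(73)
  X <- matrix(runif(80, 0.2, 1), 20, 4)
  m <- nnls_fit(X, c("a", "a", "b", "b"))
  pred <- nnls_predict(m, X[, 3, drop = FALSE])
  expect_equal(pred$labels, "b")
  expect_equal(drop(pred$coefficients), c(0, 0, 1, 0), tolerance = 1e-6)
})

test_that("both decision rules separate well-separated Gaussian classes", {
  # two non-negative Gaussian classes, mean separation 5 sigma
  set.seed(74)
  m <- 20
  mu1 <- runif(m, 2, 3)
  mu2 <- mu1 + 5 * 0.3 * sample(c(-1, 1), m, TRUE)
  make <- function(n) cbind(matrix(rnorm(m * n, mu1, 0.3), m),
                            matrix(rnorm(m * n, mu2, 0.3), m))
  Xtr <- make(30)   # 30 training samples per class
  Xte <- make(30)   # 30 test samples per class
  lab_tr <- rep(c(1, 2), each = 30)
  lab_te <- rep(c(1, 2), each = 30)
  for (rule in c("min_class_residual", "max_class_coefficient")) {
    mod <- nnls_fit(Xtr, lab_tr, decision_rule = rule)
    acc <- mean(nnls_predict(mod, Xte)$labels == lab_te)
    expect_equal(acc, 1.0)
  }
})

test_that("predictions depend on inner products only and on scale
           invariance", {
  set.seed(75)
  g <- generate_synthetic(30, 20, 2, cluster_sizes = c(10, 10), seed = 76)
  X <- g$data$X
  m1 <- nnls_fit(X[, 1:16], g$labels[1:16])
  m2 <- nnls_fit(5 * X[, 1:16], g$labels[1:16])
  expect_equal(m1$gram, m2$gram, tolerance = 1e-12)
  p1 <- nnls_predict(m1, X[, 17:20])
  p2 <- nnls_predict(m2, 5 * X[, 17:20])
  expect_equal(p1$labels, p2$labels)
})

test_that("orthonormal training samples give clipped-projection
           coefficients", {
  # lambda = 0, complete data, orthonormal training set: the NNQP decouples
  X <- diag(4)
  m <- nnls_fit(X, c(0, 0, 1, 1))
  s <- matrix(c(0.8, 0, 0.6, 0), 4, 1)
  pred <- nnls_predict(m, s)
  expect_equal(drop(pred$coefficients), pmax(drop(crossprod(X, s)), 0),
               tolerance = 1e-8)
})

test_that("cross_validate is deterministic and returns folds x runs
           accuracies", {
  g <- generate_synthetic(40, 24, 2, cluster_sizes = c(12, 12), seed = 77)
  cv1 <- cross_validate(g$data$X, g$labels, folds = 4, runs = 5, seed = 9)
  cv2 <- cross_validate(g$data$X, g$labels, folds = 4, runs = 5, seed = 9)
  expect_identical(cv1$fold_accuracies, cv2$fold_accuracies)
  expect_equal(dim(cv1$fold_accuracies), c(5L, 4L))
  expect_equal(cv1$mean_accuracy, mean(cv1$fold_accuracies))
  expect_true(all(cv1$fold_accuracies >= 0 & cv1$fold_accuracies <= 1))
  # the paper's protocol shape: 4 folds x 20 runs = 80 accuracies
  cv3 <- cross_validate(g$data$X, g$labels, folds = 4, runs = 20, seed = 1)
  expect_length(as.vector(cv3$fold_accuracies), 80L)
})

test_that("a majority-vote classifier scores 0.5 on balanced two-class
           data", {
  g <- generate_synthetic(10, 24, 2, cluster_sizes = c(12, 12), seed = 78)
  majority <- function(X_tr, labels, S)
    rep(names(which.max(table(labels))), ncol(S))
  cv <- cross_validate(g$data$X, as.character(g$labels), folds = 4,
                       runs = 3, classifier = majority, seed = 2)
  expect_equal(cv$mean_accuracy, 0.5, tolerance = 0.05)
})

test_that("mask_missing hits the exact count and rate 0 changes nothing", {
  X <- matrix(runif(200), 20, 10)
  Xm <- mask_missing(X, 0.3, seed = 3)
  expect_equal(sum(is.na(Xm)), round(0.3 * 200))
  expect_error(mask_missing(X, 1.2), "\\[0, 1\\)")
  me <- missingness_experiment(X + 0.1, rep(1:2, each = 5), rates = 0,
                               folds = 2, seed = 4)
  expect_equal(me$mean_accuracy[me$strategy == "ignore"],
               me$mean_accuracy[me$strategy == "zero_impute"])
})

test_that("the missingness experiment reports both strategies at every
           rate", {
  g <- generate_synthetic(120, 24, 2, cluster_sizes = c(12, 12),
                          noise_variance = 1, sign_mode = "mixed",
                          seed = 42)
  X <- normalize_mean0_std1(g$data$X)
  me <- missingness_experiment(X, g$labels, rates = c(0.1, 0.4), folds = 3,
                               runs = 1, seed = 5)
  expect_equal(nrow(me), 4L)
  expect_setequal(me$strategy, c("ignore", "zero_impute"))
  expect_true(all(me$mean_accuracy >= 0 & me$mean_accuracy <= 1))
})

test_that("NNLS degrades no faster than 1-NN under heavy noise", {
  g <- generate_synthetic(100, 60, 2, cluster_sizes = c(30, 30),
                          sign_mode = "mixed", seed = 42)
  X <- normalize_mean0_std1(g$data$X)
  ne <- noise_experiment(X, g$labels, variances = c(2, 4), n_seeds = 8,
                         seed = 1)
  for (v in c(2, 4)) {
    nnls_acc <- ne$mean_accuracy[ne$variance == v & ne$classifier == "nnls"]
    knn_acc <- ne$mean_accuracy[ne$variance == v & ne$classifier == "1nn"]
    expect_gte(nnls_acc, knn_acc)
  }
})
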