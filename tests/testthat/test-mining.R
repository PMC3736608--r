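# Clustering, rank selection, biclustering, feature extraction/selection.

test_that("assign_clusters takes the argmax with low-index ties", {
  r <- assign_clusters(rbind(c(0.9, 0.1), c(0.1, 0.8)))
  expect_equal(r$labels, c(1L, 2L))
  expect_equal(assign_clusters(matrix(c(0.5, 0.5), 2, 1))$labels, 1L)
  expect_warning(assign_clusters(matrix(0, 2, 1)), "all-zero")
  expect_error(assign_clusters(matrix(c(-1, 1), 2, 1)), "non-negative")
})

test_that("assign_clusters is invariant to positive column rescaling", {
  set.seed(50)
  Y <- matrix(runif(30), 3, 10)
  sc <- runif(10, 0.1, 10)
  expect_equal(assign_clusters(Y)$labels,
               assign_clusters(sweep(Y, 2, sc, "*"))$labels)
})

test_that("NMF clustering recovers well-separated planted clusters", {
  g <- generate_synthetic(30, 24, 3, seed = 51)
  fit <- nmf_nnls(g$data, 3, fit_options(seed = 52, max_iter = 200))
  agree <- permuted_agreement(assign_clusters(fit$Y)$labels, g$labels)
  expect_gt(agree, 0.95)
})

test_that("dispersion coefficient behaves per its closed form", {
  n <- 6
  expect_equal(dispersion_coefficient(matrix(1, n, n)), 1)
  C <- matrix(0.5, n, n); diag(C) <- 1
  expect_equal(dispersion_coefficient(C), n / n^2)
  # binary consensus gives exactly 1; anything else strictly less
  set.seed(53)
  B <- matrix(sample(0:1, n * n, TRUE), n)
  expect_equal(dispersion_coefficient(B), 1)
  expect_lt(dispersion_coefficient(matrix(0.3, n, n)), 1)
  expect_error(dispersion_coefficient(matrix(2, 2, 2)), "\\[0, 1\\]")
})

test_that("choose_best_k picks the planted rank", {
  g <- generate_synthetic(30, 24, 3, seed = 54)
  res <- choose_best_k(g$data, 2:5, runs = 10,
                       opts = fit_options(seed = 55, max_iter = 100))
  expect_equal(res$best_k, 3)
  expect_error(choose_best_k(g$data, integer(0)), "non-empty")
  C <- res$summaries$k3$C
  expect_equal(C, t(C))
  expect_equal(diag(C), rep(1, 24))
})

test_that("biclustering recovers planted blocks exactly", {
  # two disjoint blocks (3 high-expression features x 6 samples each) on a
  # background of silent features; the mean + z*sd row rule needs the block
  # features to be a minority of the rows
  set.seed(56)
  B1 <- matrix(runif(3 * 6, 1.5, 2), 3, 6)
  B2 <- matrix(runif(3 * 6, 1.5, 2), 3, 6)
  X <- rbind(cbind(B1, matrix(0, 3, 6)), cbind(matrix(0, 3, 6), B2),
             matrix(0, 4, 12))
  res <- bicluster(X, 2, row_z = 1, opts = fit_options(seed = 57,
                                                       max_iter = 200))
  rows <- lapply(res$biclusters, `[[`, "row_members")
  cols <- lapply(res$biclusters, `[[`, "col_members")
  # match factors to blocks by their column members
  o <- if (1 %in% cols[[1]]) 1:2 else 2:1
  expect_equal(sort(rows[[o[1]]]), 1:3)
  expect_equal(sort(rows[[o[2]]]), 4:6)
  expect_equal(sort(cols[[o[1]]]), 1:6)
  expect_equal(sort(cols[[o[2]]]), 7:12)

  # column members always partition the samples
  allc <- sort(unlist(cols))
  expect_equal(allc, 1:12)

  # an extreme row threshold empties the feature sets
  res2 <- suppressWarnings(bicluster(X, 2, row_z = 1e6,
                                     opts = fit_options(seed = 57,
                                                        max_iter = 50)))
  expect_true(all(lengths(lapply(res2$biclusters, `[[`,
                                 "row_members")) == 0))
})

test_that("feature extraction: shape contracts, exact rank, determinism", {
  g <- generate_synthetic(20, 12, 3, seed = 58)
  sp <- extract_features_train(g$data, 3,
                               opts = fit_options(seed = 59,
                                                  max_iter = 300,
                                                  tol = 1e-12))
  expect_equal(dim(sp$Y_tr), c(3L, 12L))
  expect_equal(dim(sp$A), c(20L, 3L))
  expect_gte(min(sp$A), 0)
  expect_gte(min(sp$Y_tr), 0)
  expect_lt(norm(g$data$X - sp$A %*% sp$Y_tr, "F") / norm(g$data$X, "F"),
            1e-5)
  sp2 <- extract_features_train(g$data, 3,
                                opts = fit_options(seed = 59,
                                                   max_iter = 300,
                                                   tol = 1e-12))
  expect_identical(sp$A, sp2$A)
  expect_error(extract_features_train(g$data, 3, method = "bogus"),
               "supported")
})

test_that("feature-space projection is exact on the basis and linear", {
  g <- generate_synthetic(20, 12, 3, seed = 60)
  sp <- extract_features_train(g$data, 3, opts = fit_options(seed = 61,
                                                             max_iter = 200))
  expect_equal(extract_features_test(sp, sp$A), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(extract_features_test(sp, 2 * sp$A), 2 * diag(3),
               tolerance = 1e-8, ignore_attr = TRUE)
  # re-projection of the training data matches the training coefficients
  Yuk <- extract_features_test(sp, g$data$X)
  o1 <- 0.5 * norm(g$data$X - sp$A %*% sp$Y_tr, "F")^2
  o2 <- 0.5 * norm(g$data$X - sp$A %*% Yuk, "F")^2
  expect_lt(abs(o1 - o2), 1e-6)
  expect_error(extract_features_test(sp, matrix(0, 7, 2)), "features")
})

test_that("kernel feature extraction projects through inner products", {
  g <- generate_synthetic(15, 10, 2, seed = 62)
  sp <- extract_features_train(g$data, 2, method = "kernel-seminmf",
                               spec = kernel_spec("linear"),
                               opts = fit_options(seed = 63,
                                                  max_iter = 100))
  Yuk <- extract_features_test(sp, g$data$X)
  expect_equal(dim(Yuk), c(2L, 10L))
  expect_gte(min(Yuk), 0)
})

test_that("entropy scores are 1 for one-hot rows, 0 for uniform rows", {
  A <- rbind(c(1, 0, 0), c(1, 1, 1) / 3, c(0.5, 0.5, 0))
  es <- select_features_entropy(A, threshold_sd = 100)
  expect_equal(es$score[1], 1)
  expect_equal(es$score[2], 0)
  # two equal weights among k = 3 factors: entropy 1 bit of log2(3) possible
  expect_equal(es$score[3], 1 - 1 / log2(3), tolerance = 1e-12)
  expect_true(all(es$score >= 0 & es$score <= 1))
  expect_error(select_features_entropy(matrix(1, 3, 1)), "k >= 2")
})

test_that("entropy selection recovers exactly the planted one-hot rows", {
  set.seed(64)
  hot <- diag(3)[rep(1:3, length.out = 10), ]
  A <- rbind(hot, matrix(1 / 3, 90, 3))
  es <- select_features_entropy(A, threshold_sd = 2)
  expect_equal(sort(unlist(es$selected)), 1:10)
  # each selected feature is attached to its argmax factor
  expect_true(all(unlist(lapply(seq_len(3), function(q)
    apply(A[es$selected[[q]], , drop = FALSE], 1, which.max) == q))))
})

test_that("entropy selection excludes and reports all-zero rows", {
  A <- rbind(c(1, 0), c(0, 0), c(0.5, 0.5))
  es <- select_features_entropy(A, threshold_sd = 0.5)
  expect_equal(es$zero_rows, 2L)
  expect_true(is.na(es$score[2]))
})
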