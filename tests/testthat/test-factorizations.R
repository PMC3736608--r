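# Linear factorization variants: exact recovery, monotonicity, reductions.

test_that("multiplicative NMF fits exact low-rank non-negative inputs", {
  X1 <- outer(c(1, 2), c(3, 1))
  f1 <- nmf_multiplicative(X1, 1,
                           fit_options(seed = 1, max_iter = 2000,
                                       tol = 1e-14))
  expect_lt(tail(f1$objective_trace, 1), 1e-10)

  X2 <- diag(c(1, 2, 3, 4)) + 0.01
  f2 <- nmf_nnls(X2, 4, fit_options(seed = 2, max_iter = 200, tol = 1e-12))
  expect_lt(tail(f2$objective_trace, 1), 1e-8)
})

test_that("multiplicative NMF objective is non-increasing", {
  set.seed(11)
  for (t in 1:5) {
    X <- matrix(runif(200), 20, 10)
    f <- nmf_multiplicative(X, 3, fit_options(seed = t, max_iter = 150))
    expect_true(trace_nonincreasing(f$objective_trace))
    expect_gte(min(f$A), 0)
    expect_gte(min(f$Y), 0)
  }
})

test_that("multiplicative NMF rejects mixed-sign input with guidance", {
  expect_error(nmf_multiplicative(matrix(rnorm(20), 4, 5), 2), "seminmf")
})

test_that("alternating NNLS recovers planted factors and is deterministic", {
  # identifiable planted basis: factor-specific one-hot rows
  g <- generate_synthetic(10, 8, 2, seed = 3)
  X <- g$data$X
  opts <- fit_options(seed = 3, max_iter = 400, tol = 1e-12)
  fit <- nmf_nnls(X, 2, opts)
  expect_lt(relative_residual(X, fit), 1e-6)
  expect_gt(permuted_factor_correlation(fit$A, g$A), 0.999)
  fit2 <- nmf_nnls(X, 2, opts)
  expect_identical(fit$A, fit2$A)
  expect_identical(fit$Y, fit2$Y)
})

test_that("semi-NMF handles mixed signs; A-update is exact least squares", {
  set.seed(13)
  # fixed Y = I (via init and a single iteration): A must equal X exactly
  X <- matrix(rnorm(24), 4, 6)
  k <- 3
  Y0 <- cbind(diag(k), matrix(0, k, 3))  # pseudoinverse well defined
  fit1 <- seminmf(X, k, "nnls", fit_options(max_iter = 1,
                                            init = list(Y = Y0)))
  expect_equal(fit1$A, X %*% t(Y0) %*% solve(Y0 %*% t(Y0)),
               tolerance = 1e-10)

  # noiseless mixed-sign recovery
  A_true <- matrix(rnorm(30), 15, 2)
  Y_true <- matrix(runif(20), 2, 10)
  X2 <- A_true %*% Y_true
  fit2 <- seminmf(X2, 2, "nnls", fit_options(seed = 5, max_iter = 500,
                                             tol = 1e-13))
  expect_lt(relative_residual(X2, fit2), 1e-6)
  expect_gte(min(fit2$Y), 0)

  # the exact NNLS path reaches at least the multiplicative path's objective
  X3 <- matrix(rnorm(150), 15, 10)
  f_n <- seminmf(X3, 3, "nnls", fit_options(seed = 6, max_iter = 500))
  f_m <- seminmf(X3, 3, "mult", fit_options(seed = 6, max_iter = 2000))
  expect_lte(tail(f_n$objective_trace, 1),
             tail(f_m$objective_trace, 1) * 1.05)
  expect_error(seminmf(X3, 10), "k < n")
})

test_that("sparse NMF: unit-norm basis, lambda path, and Eq.(10) Y-step", {
  set.seed(14)
  X <- matrix(runif(200), 20, 10)
  fit <- sparse_nmf(X, 3, vsmf_config(lambda_sparse = 0.5),
                    opts = fit_options(seed = 7, max_iter = 100))
  expect_equal(sqrt(colSums(fit$A^2)), rep(1, 3), tolerance = 1e-8)

  # sparsity of Y is non-decreasing along the lambda path
  sp <- vapply(c(0, 0.1, 1, 10), function(l)
    matrix_sparsity(sparse_nmf(X, 3, vsmf_config(lambda_sparse = l),
                               opts = fit_options(seed = 7,
                                                  max_iter = 80))$Y),
    numeric(1))
  expect_true(all(diff(sp) >= 0))

  # Y-step with orthonormal basis reduces to soft thresholding
  ystep <- solve_nnqp(diag(2), 2 - diag(2) %*% c(3, 1))$Z
  expect_equal(drop(ystep), c(1, 0))

  # lambda = 0 reduces to nmf_nnls up to per-column rescaling
  opts0 <- fit_options(seed = 8, max_iter = 500, tol = 1e-15)
  f_sparse <- sparse_nmf(X, 3, vsmf_config(lambda_sparse = 0), opts = opts0)
  f_plain <- nmf_nnls(X, 3, opts0)
  expect_equal(tail(f_sparse$objective_trace, 1),
               tail(f_plain$objective_trace, 1), tolerance = 1e-6)
})

test_that("Kim-Park sparse NMF and the sparse semi-NMF run and converge", {
  set.seed(15)
  X <- matrix(runif(200), 20, 10)
  f_kp <- sparse_nmf(X, 3, vsmf_config(lambda_sparse = 0.2, eta = 0.1),
                     variant = "kim_park",
                     opts = fit_options(seed = 9, max_iter = 80))
  expect_true(trace_nonincreasing(f_kp$objective_trace, 1e-8))
  Xm <- matrix(rnorm(200), 20, 10)
  f_semi <- sparse_nmf(Xm, 3, vsmf_config(lambda_sparse = 0.2),
                       semi = TRUE,
                       opts = fit_options(seed = 10, max_iter = 80))
  expect_gte(min(f_semi$Y), 0)
  expect_equal(sqrt(colSums(f_semi$A^2)), rep(1, 3), tolerance = 1e-8)
})

test_that("VSMF multiplicative rules reduce to standard NMF at zero penalty", {
  set.seed(16)
  X <- matrix(runif(200), 20, 10)
  A0 <- matrix(runif(60), 20, 3)
  Y0 <- matrix(runif(30), 3, 10)
  o1 <- fit_options(max_iter = 1, init = list(A = A0, Y = Y0))
  std <- nmf_multiplicative(X, 3, o1)
  v <- vsmf(X, 3, vsmf_config(), "mult", o1)
  expect_equal(std$A, v$A, tolerance = 1e-12)
  expect_equal(std$Y, v$Y, tolerance = 1e-12)
})

test_that("VSMF multiplicative update fixes exact factorizations", {
  set.seed(17)
  A0 <- matrix(runif(30, 0.2, 1), 10, 3)
  Y0 <- matrix(runif(18, 0.2, 1), 3, 6)
  X <- A0 %*% Y0
  v <- vsmf(X, 3, vsmf_config(), "mult",
            fit_options(max_iter = 1, init = list(A = A0, Y = Y0)))
  expect_equal(v$A, A0, tolerance = 1e-12)
  expect_equal(v$Y, Y0, tolerance = 1e-12)
})

test_that("VSMF active-set path handles sign-free basis with l1 sparsity", {
  # two planted temporal patterns, one rising and one falling, mixed sign
  set.seed(18)
  tpts <- seq(-1, 1, length.out = 16)
  rising <- tpts
  falling <- -tpts + 0.2
  A_true <- cbind(rising, falling)
  Y_true <- matrix(runif(2 * 12, 0, 1), 2, 12)
  X <- A_true %*% Y_true + matrix(rnorm(16 * 12, sd = 0.02), 16)
  fit <- vsmf(X, 2, vsmf_config(alpha1 = 0.01, lambda2 = 0.01,
                                t1 = FALSE, t2 = TRUE),
              "active_set", fit_options(seed = 11, max_iter = 120))
  expect_gte(min(fit$Y), 0)
  corr <- permuted_factor_correlation(abs(fit$A), abs(A_true))
  expect_gt(permuted_factor_correlation(fit$A, A_true), 0.9)
  expect_true(trace_nonincreasing(fit$objective_trace))
  expect_error(vsmf(X, 2, vsmf_config(t1 = FALSE), "mult"), "active_set")
})

test_that("convex NMF yields simplex weights and centroid-like bases", {
  set.seed(19)
  c1 <- matrix(rnorm(5 * 10, mean = 0), 5, 10) * 0.2 + c(5, 0, 0, 2, 1)
  c2 <- matrix(rnorm(5 * 10, mean = 0), 5, 10) * 0.2 + c(0, 4, 3, 0, 1)
  X <- cbind(c1, c2)
  fit <- convex_nmf(X, 2, fit_options(seed = 12, max_iter = 600))
  expect_equal(colSums(fit$extra$W), c(1, 1), tolerance = 1e-8)
  cents <- cbind(rowMeans(c1), rowMeans(c2))
  d <- sapply(1:2, function(q) min(
    sqrt(sum((fit$A[, q] - cents[, 1])^2)) / sqrt(sum(cents[, 1]^2)),
    sqrt(sum((fit$A[, q] - cents[, 2])^2)) / sqrt(sum(cents[, 2]^2))))
  expect_lt(max(d), 0.1)
})

test_that("convex NMF objective is monotone on non-negative data", {
  set.seed(20)
  X <- matrix(runif(150), 10, 15)
  fit <- convex_nmf(X, 3, fit_options(seed = 13, max_iter = 150))
  expect_true(trace_nonincreasing(fit$objective_trace))
})

test_that("orthogonal tri-factor NMF finds near-orthogonal bases on
           block-diagonal data", {
  set.seed(21)
  B1 <- matrix(runif(25, 1, 2), 5)
  B2 <- matrix(runif(25, 1, 2), 5)
  X <- rbind(cbind(B1, matrix(0, 5, 5)), cbind(matrix(0, 5, 5), B2))
  fit <- orth_nmf(X, 2, fit_options(seed = 14, max_iter = 1500,
                                    tol = 1e-12))
  expect_lt(fit$extra$orth_dev_A, 0.05)
  expect_true(trace_nonincreasing(fit$objective_trace))
  expect_gte(min(fit$extra$S), 0)

  # S absorbs a rescaling of X; orthonormality deviations are unchanged
  fit10 <- orth_nmf(10 * X, 2, fit_options(seed = 14, max_iter = 1500,
                                           tol = 1e-12))
  expect_equal(sum(fit10$extra$S) / sum(fit$extra$S), 10, tolerance = 0.05)
  expect_equal(fit10$extra$orth_dev_A, fit$extra$orth_dev_A,
               tolerance = 1e-3)
})

test_that("weighted NMF reduces to the standard rules under a full mask", {
  set.seed(22)
  X <- matrix(runif(200), 20, 10)
  A0 <- matrix(runif(60), 20, 3)
  Y0 <- matrix(runif(30), 3, 10)
  for (iters in c(1, 25)) {
    o <- fit_options(max_iter = iters, init = list(A = A0, Y = Y0))
    std <- nmf_multiplicative(X, 3, o)
    w <- weighted_nmf(X, 3, o)
    expect_equal(std$A, w$A, tolerance = 1e-12)
    expect_equal(std$Y, w$Y, tolerance = 1e-12)
  }
})

test_that("weighted NMF ignores masked cells and imputes rank-1 data", {
  a <- c(1.2, 0.7, 1.9, 0.4, 1.1)
  y <- c(0.9, 1.4, 0.6, 1.8, 1.0)
  X_true <- outer(a, y)
  X <- X_true
  X[2, 3] <- NaN
  fit <- weighted_nmf(X, 1, fit_options(seed = 15, max_iter = 4000,
                                        tol = 1e-14))
  expect_lt(abs(fit$extra$imputed[2, 3] - X_true[2, 3]), 1e-3)

  # the stored value behind the mask is irrelevant
  X2 <- X_true
  X2[2, 3] <- NaN
  d1 <- data_matrix(X)
  d2 <- data_matrix(X2)
  d2$X[2, 3] <- 99  # garbage behind the mask
  f1 <- weighted_nmf(d1, 1, fit_options(seed = 15, max_iter = 50))
  f2 <- weighted_nmf(d2, 1, fit_options(seed = 15, max_iter = 50))
  expect_identical(f1$A, f2$A)
})

test_that("noiseless planted factorizations are recovered across seeds", {
  set.seed(23)
  ok <- 0
  for (s in 1:10) {
    g <- generate_synthetic(25, 20, 3, seed = s)
    fit <- nmf_nnls(g$data, 3, fit_options(seed = s + 100, max_iter = 400,
                                           tol = 1e-12))
    if (relative_residual(g$data$X, fit) < 1e-5 &&
        permuted_factor_correlation(fit$A, g$A) > 0.99)
      ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("the omnibus nmf() dispatcher validates method names", {
  X <- matrix(runif(40), 8, 5)
  expect_error(nmf(X, 2, method = "nope"), "supported")
  fit <- nmf(X, 2, method = "nmf", opts = fit_options(seed = 1,
                                                      max_iter = 50))
  expect_s3_class(fit, "nmf_fit")
})
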