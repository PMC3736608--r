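# Kernelized factorizations. The key identity: with the least-squares basis
# update A = X Y^+, the coefficient update only needs
# A^T A = (Y^+)^T X^T X Y^+ and A^T X = (Y^+)^T X^T X, i.e. the Gram matrix
# X^T X alone. Replacing it by any kernel matrix K(X, X) yields the kernel
# variants, which never materialize the basis.

#' Specify a kernel function
#'
#' @param name `"linear"`, `"rbf"`, `"polynomial"` or `"precomputed"`.
#' @param sigma RBF bandwidth (feature-space units); `NULL` means the median
#'   pairwise distance heuristic is applied when the kernel is evaluated.
#' @param degree polynomial degree (integer `>= 1`).
#' @param coef0 polynomial offset.
#' @return A list of class `kernel_spec`.
#' @export
kernel_spec <- function(name = c("linear", "rbf", "polynomial",
                                 "precomputed"),
                        sigma = NULL, degree = 2L, coef0 = 1) {
  name <- match.arg(name)
  if (name == "rbf" && !is.null(sigma) && sigma <= 0)
    stop("sigma must be > 0 for the RBF kernel")
  if (name == "polynomial" &&
      (degree < 1 || degree != as.integer(degree)))
    stop("degree must be an integer >= 1")
  structure(list(name = name, sigma = sigma, degree = as.integer(degree),
                 coef0 = coef0),
            class = "kernel_spec")
}

#' Compute a kernel matrix between two sample sets
#'
#' Samples are columns. `linear` gives `A^T B`; `rbf` gives
#' `exp(-||a - b||^2 / (2 sigma^2))` pairwise (with `sigma` defaulting to the
#' median pairwise distance between the columns of `A`); `polynomial` gives
#' `(A^T B + coef0)^degree` elementwise.
#'
#' @param A,B matrices with samples in columns sharing the feature dimension.
#' @param spec a [kernel_spec()].
#' @return The p x q kernel matrix `K(A, B)`.
#' @export
compute_kernel_matrix <- function(A, B = A, spec = kernel_spec("linear")) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B))
    stop("A and B must share the feature dimension: ",
         nrow(A), " vs ", nrow(B))
  switch(spec$name,
    linear = crossprod(A, B),
    polynomial = (crossprod(A, B) + spec$coef0)^spec$degree,
    rbf = {
      d2 <- outer(colSums(A * A), colSums(B * B), "+") - 2 * crossprod(A, B)
      d2[d2 < 0] <- 0
      sigma <- spec$sigma
      if (is.null(sigma)) {
        dA <- sqrt(pmax(outer(colSums(A * A), colSums(A * A), "+") -
                          2 * crossprod(A), 0))
        med <- stats::median(dA[upper.tri(dA)])
        sigma <- if (is.finite(med) && med > 0) med else 1
      }
      exp(-d2 / (2 * sigma^2))
    },
    precomputed = stop("precomputed kernels are passed directly as K"))
}

# Validate symmetry, repair tiny negative eigenvalues, error on real
# indefiniteness.
check_gram <- function(K, tol = 1e-8) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("K must be square")
  if (max(abs(K - t(K))) > tol * max(1, max(abs(K))))
    stop("K is not symmetric beyond tolerance ", tol)
  K <- (K + t(K)) / 2
  eg <- eigen(K, symmetric = TRUE)
  lmax <- max(eg$values, 0)
  if (min(eg$values) < -tol * max(1, lmax))
    stop("K is not positive semi-definite (eigenvalue ", min(eg$values),
         "); add jitter to the diagonal or check the kernel")
  if (any(eg$values < 0)) {
    v <- pmax(eg$values, 0)
    K <- eg$vectors %*% (v * t(eg$vectors))
    K <- (K + t(K)) / 2
  }
  K
}

#' Kernel semi-NMF
#'
#' Factorizes implicitly `Phi(X) ~ A Y` with `Y >= 0`, using only the kernel
#' matrix `K = K(X, X)`: each iteration forms the pseudoinverse `Y^+`, from
#' which `A^T A = (Y^+)^T K Y^+` and `A^T Phi(X) = (Y^+)^T K`, and updates
#' `Y` either by an exact NNQP solve (`algo = "nnls"`; with
#' `lambda_sparse > 0` this is the sparse kernel semi-NMF, the l1 weight
#' entering the linear term) or by the square-root multiplicative semi-NMF
#' rule (`algo = "mult"`). The basis is never materialized; with the linear
#' kernel `K = X^T X` the iterates coincide with [seminmf()].
#'
#' @param K symmetric positive semi-definite kernel matrix (n x n).
#' @param k inner dimension, `k < n`.
#' @param algo `"nnls"` or `"mult"`.
#' @param lambda_sparse non-negative l1 weight on the coefficients
#'   (`algo = "nnls"` only).
#' @param opts [fit_options()].
#' @return An object of class `kernel_nmf_fit`: list with the coefficient
#'   matrix `Y`, `pseudo` (`Y^+`), `gram_train`, `objective_trace`,
#'   `iterations`, `converged`. The objective is
#'   `0.5 * ||Phi(X) - A Y||_F^2` (plus the l1 term), evaluated through `K`.
#' @export
kernel_seminmf <- function(K, k, algo = c("nnls", "mult"), lambda_sparse = 0,
                           opts = fit_options()) {
  algo <- match.arg(algo)
  if (lambda_sparse < 0) stop("lambda_sparse must be >= 0")
  K <- check_gram(K)
  n <- ncol(K)
  if (k > n) stop("kernel semi-NMF needs k <= n")
  objective <- function(Y, H, AtX) {
    0.5 * (sum(diag(K)) - 2 * sum(AtX * Y) + sum((H %*% Y) * Y)) +
      lambda_sparse * sum(Y)
  }
  run_restarts(opts, function(seed) {
    Y <- if (!is.null(opts$init$Y)) as.matrix(opts$init$Y)
         else with_seed(seed, matrix(stats::runif(k * n), k, n))
    trace <- numeric(0)
    converged <- FALSE
    H <- NULL; AtX <- NULL
    for (iter in seq_len(opts$max_iter)) {
      Yp <- pinv_ridge(Y)                 # n x k
      H <- t(Yp) %*% K %*% Yp             # A^T A
      H <- (H + t(H)) / 2
      AtX <- t(Yp) %*% K                  # A^T Phi(X)
      if (algo == "nnls") {
        Y <- solve_nnqp(H, lambda_sparse - AtX, check = FALSE)$Z
      } else {
        Y <- Y * sqrt((pospart(AtX) + negpart(H) %*% Y) /
                        guard_den(negpart(AtX) + pospart(H) %*% Y))
      }
      f <- objective(Y, H, AtX)
      trace <- c(trace, f)
      if (iter > 1 && rel_change_small(trace[iter - 1L], f, opts$tol)) {
        converged <- TRUE
        break
      }
    }
    structure(list(Y = Y, k = as.integer(k), pseudo = pinv_ridge(Y),
                   gram_train = K, objective_trace = trace,
                   iterations = length(trace), converged = converged,
                   algo = algo, lambda_sparse = lambda_sparse),
              class = "kernel_nmf_fit")
  })
}

#' @export
print.kernel_nmf_fit <- function(x, ...) {
  cat("kernel NMF fit: k =", x$k, "on", ncol(x$Y), "samples (", x$algo,
      ")\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(iteration cap reached)", "\n")
  cat("  final objective:", format(utils::tail(x$objective_trace, 1)), "\n")
  invisible(x)
}

#' Kernel convex NMF
#'
#' Convex NMF expressed through the kernel matrix only: the implicit basis is
#' `Phi(X) W` with `W >= 0` columns on the simplex, and the multiplicative
#' updates use the positive/negative parts of `K`. With `K = X^T X` this
#' reproduces [convex_nmf()] exactly.
#'
#' @inheritParams kernel_seminmf
#' @return An `nmf_fit` with `extra$W` (n x k) and `Y` (k x n); the `A` slot
#'   is empty because the basis lives in feature space.
#' @export
kernel_convex_nmf <- function(K, k, opts = fit_options()) {
  K <- check_gram(K)
  if (k > ncol(K)) stop("kernel convex NMF needs k <= n")
  fit <- convex_core(K, k, opts)
  fit$method <- "kernel-convex-nmf"
  fit
}

#' NMF decomposition of a kernel matrix
#'
#' Runs the standard multiplicative NMF on the kernel matrix itself,
#' `K ~ A Y` with `A` (n x k) and `Y` (k x n) non-negative. This requires a
#' kernel with non-negative entries (e.g. RBF); for mixed-sign Gram matrices
#' use [kernel_seminmf()].
#'
#' @inheritParams kernel_seminmf
#' @return An `nmf_fit` for the factorization of `K`.
#' @export
kernel_nmf_decompose <- function(K, k, opts = fit_options()) {
  K <- as.matrix(K)
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
    stop("K must be symmetric")
  if (min(K) < 0)
    stop("K has negative entries; decompose mixed-sign kernels with ",
         "kernel_seminmf()")
  fit <- nmf_multiplicative(data_matrix(K), k, opts)
  fit$method <- "kernel-nmf-decompose"
  fit
}
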