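# Core containers shared across the toolbox: the data matrix (with missing
# -value mask and sign mode), fit options, the VSMF penalty configuration,
# and the factorization result.

#' Wrap a feature-by-sample matrix for factorization
#'
#' Rows are features (genes), columns are samples. `NaN`/`NA` entries are
#' interpreted as missing and recorded in a binary observation mask; the sign
#' mode (`"non-negative"` or `"mixed"`) is detected from the observed entries
#' unless given, and determines which factorization variants accept the data.
#'
#' @param X numeric matrix (m features x n samples), possibly with `NaN`.
#' @param sign_mode `"non-negative"`, `"mixed"`, or `NULL` to detect.
#' @return An object of class `data_matrix` with fields `X`, `mask`
#'   (1 = observed) and `sign_mode`.
#' @export
data_matrix <- function(X, sign_mode = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be a numeric matrix")
  mask <- 1 - is.na(X)
  obs <- X[mask == 1]
  if (!length(obs)) stop("X has no observed entries")
  detected <- if (min(obs) >= 0) "non-negative" else "mixed"
  if (is.null(sign_mode)) {
    sign_mode <- detected
  } else {
    sign_mode <- match.arg(sign_mode, c("non-negative", "mixed"))
    if (sign_mode == "non-negative" && detected == "mixed")
      stop("X has negative observed entries; sign_mode cannot be non-negative")
  }
  structure(list(X = X, mask = mask, sign_mode = sign_mode),
            class = "data_matrix")
}

#' @rdname data_matrix
#' @export
as_data_matrix <- function(X, sign_mode = NULL) {
  if (inherits(X, "data_matrix")) X else data_matrix(X, sign_mode)
}

#' @export
print.data_matrix <- function(x, ...) {
  cat("data_matrix:", nrow(x$X), "features x", ncol(x$X), "samples (",
      x$sign_mode, ")\n")
  miss <- sum(x$mask == 0)
  if (miss > 0)
    cat("  missing entries:", miss,
        sprintf("(%.1f%%)", 100 * miss / length(x$X)), "\n")
  invisible(x)
}

#' Optimization options shared by all factorizations
#'
#' @param max_iter maximum number of alternating iterations.
#' @param tol convergence threshold on the relative objective change.
#' @param seed integer seed for the random initialization; `NULL` leaves the
#'   R random number generator state untouched.
#' @param init optional list with components `A` and/or `Y` (and `S`, `W`
#'   where the variant uses them) to start from instead of random draws.
#' @param n_restart number of random restarts; the fit with the lowest final
#'   objective is kept. Restart r uses seed `seed + 1000 * (r - 1)`.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(max_iter = 500L, tol = 1e-6, seed = NULL,
                        init = NULL, n_restart = 1L) {
  stopifnot(max_iter >= 1, tol > 0, n_restart >= 1)
  structure(list(max_iter = as.integer(max_iter), tol = tol, seed = seed,
                 init = init, n_restart = as.integer(n_restart)),
            class = "fit_options")
}

#' Penalty configuration for versatile sparse matrix factorization
#'
#' Collects the regularization weights of the VSMF objective
#' \deqn{\tfrac12\|X - AY\|_F^2
#'   + \sum_i (\tfrac{\alpha_2}{2}\|a_i\|_2^2 + \alpha_1\|a_i\|_1)
#'   + \sum_i (\tfrac{\lambda_2}{2}\|y_i\|_2^2 + \lambda_1\|y_i\|_1)}
#' together with the non-negativity switches `t1` (on the basis `A`) and `t2`
#' (on the coefficients `Y`). The classic sparse-NMF parameters are carried
#' alongside: `lambda_sparse` is the coefficient l1 weight of the
#' unit-norm-basis sparse NMF, and `eta` the `||A||_F^2` weight of the
#' squared-l1 (Kim-Park-style) sparse NMF.
#'
#' @param alpha1,alpha2 l1 / l2 weights on the basis columns, `>= 0`.
#' @param lambda1,lambda2 l1 / l2 weights on the coefficient columns, `>= 0`.
#' @param t1,t2 logical: enforce `A >= 0` / `Y >= 0`.
#' @param lambda_sparse coefficient l1 weight for [sparse_nmf()], `>= 0`.
#' @param eta basis Frobenius weight for the squared-l1 sparse NMF, `>= 0`.
#' @return A list of class `vsmf_config`.
#' @export
vsmf_config <- function(alpha1 = 0, alpha2 = 0, lambda1 = 0, lambda2 = 0,
                        t1 = TRUE, t2 = TRUE, lambda_sparse = 0, eta = 0) {
  w <- c(alpha1 = alpha1, alpha2 = alpha2, lambda1 = lambda1,
         lambda2 = lambda2, lambda_sparse = lambda_sparse, eta = eta)
  if (any(!is.finite(w)) || any(w < 0))
    stop("all VSMF weights must be finite and >= 0")
  structure(list(alpha1 = alpha1, alpha2 = alpha2, lambda1 = lambda1,
                 lambda2 = lambda2, t1 = isTRUE(t1) || identical(t1, 1),
                 t2 = isTRUE(t2) || identical(t2, 1),
                 lambda_sparse = lambda_sparse, eta = eta),
            class = "vsmf_config")
}

new_nmf_fit <- function(A, Y, k, objective_trace, converged, method,
                        extra = list()) {
  structure(list(A = A, Y = Y, k = as.integer(k),
                 objective_trace = objective_trace,
                 iterations = length(objective_trace),
                 converged = converged, method = method, extra = extra),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat("NMF fit (", x$method, "): ", nrow(x$A), " x ", ncol(x$Y),
      " matrix, k = ", x$k, "\n", sep = "")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(iteration cap reached)", "\n")
  cat("  final objective:", format(utils::tail(x$objective_trace, 1)), "\n")
  if (length(x$extra))
    cat("  extra factors:", paste(names(x$extra), collapse = ", "), "\n")
  invisible(x)
}

#' Residual of a factorization
#'
#' @param fit an `nmf_fit`.
#' @param X the data matrix the fit was computed from.
#' @return The residual matrix `E = X - A Y` (for the tri-factor variant,
#'   `X - A S Y`; for convex NMF, `X - X W Y`).
#' @export
nmf_residual <- function(fit, X) {
  X <- if (inherits(X, "data_matrix")) X$X else as.matrix(X)
  X - fitted_nmf(fit)
}

fitted_nmf <- function(fit) {
  if (!is.null(fit$extra$S)) fit$A %*% fit$extra$S %*% fit$Y
  else fit$A %*% fit$Y
}

# Evaluate `code` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
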