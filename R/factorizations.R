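# Linear (non-kernel) NMF variants, each an alternating block-coordinate
# optimizer over the basis A (m x k) and the coefficients Y (k x n) of
# X ~ A Y. Multiplicative-rule variants share one arithmetic layout so that
# the documented reductions between variants hold to machine precision:
# denominators are computed as ((A %*% Y) %*% t(Y)) and crossprod(A, A %*% Y)
# in every engine.

# Multiplicative denominators are floored (not shifted) so that exact fixed
# points X = A Y are preserved by the update.
MULT_EPS <- 1e-9

guard_den <- function(D) pmax(D, MULT_EPS)

frob2 <- function(M) sum(M * M)

# Random non-negative initialization, Uniform(0,1) scaled by
# sqrt(mean(|X|)/k) so that A %*% Y starts on the scale of X.
init_factors <- function(X, k, seed, init, what = c("A", "Y")) {
  m <- nrow(X); n <- ncol(X)
  scale <- sqrt(mean(abs(X), na.rm = TRUE) / k)
  if (!is.finite(scale) || scale <= 0) scale <- 1
  with_seed(seed, {
    out <- list()
    for (nm in what) {
      if (!is.null(init[[nm]])) {
        out[[nm]] <- as.matrix(init[[nm]])
      } else {
        out[[nm]] <- switch(nm,
          A = matrix(stats::runif(m * k), m, k) * scale,
          Y = matrix(stats::runif(k * n), k, n) * scale,
          S = matrix(stats::runif(k * k), k, k) *
            max(mean(abs(X), na.rm = TRUE), .Machine$double.eps),
          W = {
            W <- matrix(stats::runif(n * k), n, k)
            sweep(W, 2, colSums(W), "/")
          })
      }
    }
    out
  })
}

check_k <- function(X, k, strict = TRUE) {
  if (k < 1 || (strict && k >= min(dim(X))) || (!strict && k > min(dim(X))))
    stop("k must satisfy 1 <= k ", if (strict) "< " else "<= ",
         "min(m, n); got k = ", k, " for a ", nrow(X), " x ", ncol(X),
         " matrix")
  invisible(k)
}

require_nonneg <- function(data, variant, alternative = "seminmf()") {
  if (data$sign_mode != "non-negative")
    stop(variant, " requires non-negative data; for mixed-sign matrices use ",
         alternative)
  invisible(data)
}

require_complete <- function(data, variant) {
  if (any(data$mask == 0))
    stop(variant, " does not handle missing values; use weighted_nmf()")
  invisible(data)
}

# Reinitialize basis columns that collapsed to zero from the residual's
# largest-norm column, so the effective rank stays k.
revive_zero_columns <- function(A, X, Y) {
  dead <- which(colSums(abs(A)) == 0)
  if (length(dead)) {
    E <- X - A %*% Y
    j <- which.max(colSums(E * E))
    for (q in dead) A[, q] <- pmax(E[, j], 0) + .Machine$double.eps
  }
  A
}

run_restarts <- function(opts, fit_fun) {
  best <- NULL
  for (r in seq_len(opts$n_restart)) {
    seed_r <- if (is.null(opts$seed)) NULL else opts$seed + 1000L * (r - 1L)
    fit <- fit_fun(seed_r)
    if (is.null(best) ||
        utils::tail(fit$objective_trace, 1) <
        utils::tail(best$objective_trace, 1))
      best <- fit
  }
  best
}

rel_change_small <- function(prev, cur, tol) {
  abs(prev - cur) <= tol * max(abs(prev), 1e-12)
}

#' Standard NMF by multiplicative update rules
#'
#' Decomposes a non-negative matrix `X` into non-negative factors `A` (basis)
#' and `Y` (coefficients) minimizing `0.5 * ||X - AY||_F^2` with the classic
#' gradient-descent-derived multiplicative rules
#' `A <- A * (X Y^T) / (A Y Y^T)` and `Y <- Y * (A^T X) / (A^T A Y)`. The
#' objective trace is non-increasing; the rules converge quickly at first but
#' are not guaranteed to reach a stationary point, for which [nmf_nnls()] is
#' preferred.
#'
#' @param data a [data_matrix()] or plain non-negative matrix
#'   (features x samples).
#' @param k inner dimension (number of basis vectors), `1 <= k < min(m, n)`.
#' @param opts [fit_options()].
#' @return An `nmf_fit` with fields `A`, `Y`, `objective_trace`,
#'   `iterations`, `converged`.
#' @export
nmf_multiplicative <- function(data, k, opts = fit_options()) {
  data <- as_data_matrix(data)
  require_nonneg(data, "nmf_multiplicative()")
  require_complete(data, "nmf_multiplicative()")
  X <- data$X
  check_k(X, k)
  run_restarts(opts, function(seed) {
    fac <- init_factors(X, k, seed, opts$init)
    A <- fac$A; Y <- fac$Y
    trace <- 0.5 * frob2(X - A %*% Y)
    converged <- FALSE
    for (iter in seq_len(opts$max_iter)) {
      A <- A * (X %*% t(Y)) / guard_den((A %*% Y) %*% t(Y))
      Y <- Y * crossprod(A, X) / guard_den(crossprod(A, A %*% Y))
      f <- 0.5 * frob2(X - A %*% Y)
      trace <- c(trace, f)
      if (rel_change_small(trace[iter], f, opts$tol)) {
        converged <- TRUE
        break
      }
    }
    new_nmf_fit(A, Y, k, trace, converged, "nmf-mult")
  })
}

#' Standard NMF by alternating non-negative least squares
#'
#' Alternates exact NNLS solves for the basis (`A^T` from
#' `X^T ~ Y^T A^T`) and the coefficients (`Y` from `X ~ A Y`) via the
#' active-set solver [solve_nnls()]. Every alternating step is an exact block
#' minimization, so the objective never increases and the algorithm converges
#' to a stationary point — this is the workhorse factorization used by the
#' clustering and feature-extraction layers by default.
#'
#' @inheritParams nmf_multiplicative
#' @return An `nmf_fit`.
#' @export
nmf_nnls <- function(data, k, opts = fit_options()) {
  data <- as_data_matrix(data)
  require_nonneg(data, "nmf_nnls()")
  require_complete(data, "nmf_nnls()")
  X <- data$X
  check_k(X, k, strict = FALSE)
  run_restarts(opts, function(seed) {
    fac <- init_factors(X, k, seed, opts$init)
    A <- fac$A; Y <- fac$Y
    trace <- 0.5 * frob2(X - A %*% Y)
    converged <- FALSE
    for (iter in seq_len(opts$max_iter)) {
      A <- t(solve_nnls(AtA = tcrossprod(Y), AtB = tcrossprod(Y, X))$Z)
      A <- revive_zero_columns(A, X, Y)
      Y <- solve_nnls(AtA = crossprod(A), AtB = crossprod(A, X))$Z
      f <- 0.5 * frob2(X - A %*% Y)
      trace <- c(trace, f)
      if (rel_change_small(trace[iter], f, opts$tol)) {
        converged <- TRUE
        break
      }
    }
    new_nmf_fit(A, Y, k, trace, converged, "nmf-nnls")
  })
}

#' Semi-NMF for mixed-sign data
#'
#' Removes the non-negativity constraint from the data and the basis: only
#' the coefficients `Y` are kept non-negative, so the method applies to any
#' real-valued `X`. With `algo = "nnls"`, the basis update is the exact least
#' squares solution `A = X Y^+` (Moore-Penrose pseudoinverse of `Y`) and the
#' coefficient update is an exact NNLS solve; with `algo = "mult"` the
#' coefficient update is the square-root multiplicative rule built from the
#' positive/negative parts of `A^T X` and `A^T A`.
#'
#' @inheritParams nmf_multiplicative
#' @param algo `"nnls"` (exact alternating updates) or `"mult"`
#'   (multiplicative coefficient rule).
#' @return An `nmf_fit` (the basis `A` may have either sign).
#' @export
seminmf <- function(data, k, algo = c("nnls", "mult"), opts = fit_options()) {
  algo <- match.arg(algo)
  data <- as_data_matrix(data)
  require_complete(data, "seminmf()")
  X <- data$X
  if (k >= ncol(X))
    stop("semi-NMF needs k < n so that the pseudoinverse of Y is defined")
  check_k(X, k, strict = FALSE)
  run_restarts(opts, function(seed) {
    Y <- init_factors(X, k, seed, opts$init, what = "Y")$Y
    A <- NULL
    trace <- numeric(0)
    converged <- FALSE
    for (iter in seq_len(opts$max_iter)) {
      A <- X %*% pinv_ridge(Y)
      if (algo == "nnls") {
        Y <- solve_nnqp(crossprod(A), -crossprod(A, X), check = FALSE)$Z
      } else {
        AtX <- crossprod(A, X)
        AtA <- crossprod(A)
        Y <- Y * sqrt((pospart(AtX) + negpart(AtA) %*% Y) /
                        guard_den(negpart(AtX) + pospart(AtA) %*% Y))
      }
      f <- 0.5 * frob2(X - A %*% Y)
      trace <- c(trace, f)
      if (iter > 1 && rel_change_small(trace[iter - 1L], f, opts$tol)) {
        converged <- TRUE
        break
      }
    }
    new_nmf_fit(A, Y, k, trace, converged, paste0("seminmf-", algo))
  })
}

pospart <- function(M) (abs(M) + M) / 2
negpart <- function(M) (abs(M) - M) / 2

# Moore-Penrose pseudoinverse of a k x n matrix with a small ridge fallback
# when Y Y^T is near-singular.
pinv_ridge <- function(Y) {
  YYt <- tcrossprod(Y)
  inv <- tryCatch(solve(YYt), error = function(e) NULL)
  if (is.null(inv)) {
    k <- nrow(YYt)
    inv <- solve(YYt + diag(1e-10 * max(sum(diag(YYt)), 1), k))
  }
  t(Y) %*% inv
}

#' Sparse NMF with l1-penalized coefficients
#'
#' Two sparse factorization models. `variant = "unit_norm"` (the default)
#' optimizes
#' `0.5 * ||X - AY||_F^2 + lambda * sum_i ||y_i||_1` subject to `Y >= 0` and
#' unit-l2-norm basis columns, by three alternating steps: an NNQP solve for
#' `Y` (Gram form `H = A^T A`, `g_i = lambda - A^T x_i`), an NNLS solve for
#' `A`, and a renormalization of the basis columns. `variant = "kim_park"`
#' optimizes the squared-l1 model
#' `0.5 * ||X - AY||_F^2 + (eta/2) * ||A||_F^2 +
#' (lambda/2) * sum_i ||y_i||_1^2` (set `squared_l1 = FALSE` for a plain l1
#' penalty). With `semi = TRUE` (unit-norm variant only) the basis is
#' unconstrained in sign and updated by least squares, giving the sparse
#' semi-NMF.
#'
#' @inheritParams nmf_multiplicative
#' @param cfg a [vsmf_config()]; `lambda_sparse` is the coefficient l1 weight
#'   and `eta` the basis Frobenius weight of the Kim-Park variant.
#' @param variant `"unit_norm"` or `"kim_park"`.
#' @param semi allow a mixed-sign basis (unit-norm variant).
#' @param squared_l1 square the per-column l1 penalty in the Kim-Park
#'   variant.
#' @return An `nmf_fit`.
#' @export
sparse_nmf <- function(data, k, cfg = vsmf_config(),
                       variant = c("unit_norm", "kim_park"), semi = FALSE,
                       squared_l1 = TRUE, opts = fit_options()) {
  variant <- match.arg(variant)
  data <- as_data_matrix(data)
  require_complete(data, "sparse_nmf()")
  lambda <- cfg$lambda_sparse
  if (lambda < 0) stop("lambda_sparse must be >= 0")
  if (variant == "kim_park" || !semi)
    require_nonneg(data, "sparse_nmf()", "sparse_nmf(semi = TRUE)")
  X <- data$X
  check_k(X, k, strict = FALSE)
  run_restarts(opts, function(seed) {
    fac <- init_factors(X, k, seed, opts$init)
    A <- fac$A; Y <- fac$Y
    if (variant == "unit_norm") A <- normalize_columns(A)
    trace <- numeric(0)
    converged <- FALSE
    penalty <- function(A, Y) {
      if (variant == "unit_norm") lambda * sum(Y)
      else cfg$eta / 2 * frob2(A) +
        lambda / 2 * (if (squared_l1) sum(colSums(Y)^2) else 2 * sum(Y))
    }
    for (iter in seq_len(opts$max_iter)) {
      if (variant == "unit_norm") {
        Y <- solve_nnqp(crossprod(A), lambda - crossprod(A, X),
                        check = FALSE)$Z
        if (semi) {
          A <- X %*% pinv_ridge(Y)
        } else {
          A <- t(solve_nnls(AtA = tcrossprod(Y),
                            AtB = tcrossprod(Y, X))$Z)
          A <- revive_zero_columns(A, X, Y)
        }
        A <- normalize_columns(A)
      } else {
        H_y <- crossprod(A) + if (squared_l1) lambda else 0
        G_y <- (if (squared_l1) 0 else lambda) - crossprod(A, X)
        Y <- solve_nnqp(H_y, G_y, check = FALSE)$Z
        H_a <- tcrossprod(Y) + diag(cfg$eta, k)
        A <- t(solve_nnqp(H_a, -(Y %*% t(X)), check = FALSE)$Z)
        A <- revive_zero_columns(A, X, Y)
      }
      f <- 0.5 * frob2(X - A %*% Y) + penalty(A, Y)
      trace <- c(trace, f)
      if (iter > 1 && rel_change_small(trace[iter - 1L], f, opts$tol)) {
        converged <- TRUE
        break
      }
    }
    new_nmf_fit(A, Y, k, trace, converged, paste0("sparse-", variant))
  })
}

normalize_columns <- function(A) {
  nrm <- sqrt(colSums(A * A))
  nrm[nrm == 0] <- 1
  sweep(A, 2, nrm, "/")
}

#' Versatile sparse matrix factorization (VSMF)
#'
#' Unifies the standard, semi- and sparse NMF models in one objective,
#' \deqn{\tfrac12\|X - AY\|_F^2
#'   + \sum_i(\tfrac{\alpha_2}{2}\|a_i\|_2^2 + \alpha_1\|a_i\|_1)
#'   + \sum_i(\tfrac{\lambda_2}{2}\|y_i\|_2^2 + \lambda_1\|y_i\|_1),}
#' with independent non-negativity switches `t1` (basis) and `t2`
#' (coefficients). `algo = "mult"` applies the multiplicative rules
#' `A <- A * (X Y^T) / (A Y Y^T + alpha2 A + alpha1)`,
#' `Y <- Y * (A^T X) / (A^T A Y + lambda2 Y + lambda1)` and requires
#' `t1 = t2 = TRUE` with non-negative data. `algo = "active_set"` updates
#' non-negative blocks by NNQP and sign-free blocks by the l1-regularized QP,
#' so any `(t1, t2)` combination is supported; each block update is an exact
#' minimization and the objective is non-increasing.
#'
#' @inheritParams nmf_multiplicative
#' @param cfg a [vsmf_config()] with the penalty weights and sign switches.
#' @param algo `"active_set"` or `"mult"`.
#' @return An `nmf_fit`.
#' @export
vsmf <- function(data, k, cfg = vsmf_config(),
                 algo = c("active_set", "mult"), opts = fit_options()) {
  algo <- match.arg(algo)
  data <- as_data_matrix(data)
  require_complete(data, "vsmf()")
  X <- data$X
  check_k(X, k, strict = FALSE)
  if (algo == "mult") {
    if (!cfg$t1 || !cfg$t2)
      stop("vsmf(algo = \"mult\") supports only t1 = t2 = TRUE; ",
           "use algo = \"active_set\" for sign-free factors")
    require_nonneg(data, "vsmf(algo = \"mult\")",
                   "vsmf(algo = \"active_set\")")
  }
  objective <- function(A, Y) {
    0.5 * frob2(X - A %*% Y) +
      cfg$alpha2 / 2 * frob2(A) + cfg$alpha1 * sum(abs(A)) +
      cfg$lambda2 / 2 * frob2(Y) + cfg$lambda1 * sum(abs(Y))
  }
  run_restarts(opts, function(seed) {
    fac <- init_factors(X, k, seed, opts$init)
    A <- fac$A; Y <- fac$Y
    trace <- objective(A, Y)
    converged <- FALSE
    for (iter in seq_len(opts$max_iter)) {
      if (algo == "mult") {
        A <- A * (X %*% t(Y)) /
          guard_den((A %*% Y) %*% t(Y) + cfg$alpha2 * A + cfg$alpha1)
        Y <- Y * crossprod(A, X) /
          guard_den(crossprod(A, A %*% Y) + cfg$lambda2 * Y + cfg$lambda1)
      } else {
        H_a <- tcrossprod(Y) + diag(cfg$alpha2, k)
        G_a <- -(Y %*% t(X))
        if (cfg$t1) {
          A <- t(solve_nnqp(H_a, cfg$alpha1 + G_a, check = FALSE)$Z)
        } else {
          A <- t(vapply(seq_len(nrow(X)), function(j)
            solve_l1qp(H_a, G_a[, j], cfg$alpha1), numeric(k)))
        }
        H_y <- crossprod(A) + diag(cfg$lambda2, k)
        G_y <- -crossprod(A, X)
        if (cfg$t2) {
          Y <- solve_nnqp(H_y, cfg$lambda1 + G_y, check = FALSE)$Z
        } else {
          Y <- vapply(seq_len(ncol(X)), function(j)
            solve_l1qp(H_y, G_y[, j], cfg$lambda1), numeric(k))
        }
      }
      f <- objective(A, Y)
      trace <- c(trace, f)
      if (rel_change_small(trace[iter], f, opts$tol)) {
        converged <- TRUE
        break
      }
    }
    new_nmf_fit(A, Y, k, trace, converged, paste0("vsmf-", algo))
  })
}

#' Convex NMF: basis vectors as convex combinations of samples
#'
#' Factorizes `X ~ X W Y` where `W` (n x k, non-negative, columns summing to
#' one) expresses each basis vector `a_q = X w_q` as a convex combination of
#' the data points, and `Y` (k x n) holds non-negative coefficients. The
#' basis columns therefore live inside the data cloud and behave like
#' cluster centroids; `X` may have mixed signs. Updates are the square-root
#' multiplicative rules built from the positive/negative parts of the Gram
#' matrix `X^T X` (the same engine powers [kernel_convex_nmf()]).
#'
#' @inheritParams nmf_multiplicative
#' @return An `nmf_fit` with `A = X W` and `extra$W`.
#' @export
convex_nmf <- function(data, k, opts = fit_options()) {
  data <- as_data_matrix(data)
  require_complete(data, "convex_nmf()")
  X <- data$X
  if (k > ncol(X)) stop("convex NMF needs k <= n")
  fit <- convex_core(crossprod(X), k, opts)
  fit$A <- X %*% fit$extra$W
  fit$method <- "convex-nmf"
  fit
}

# Shared convex-NMF engine operating on the Gram matrix only.
convex_core <- function(K, k, opts) {
  n <- nrow(K)
  Kp <- pospart(K)
  Kn <- negpart(K)
  objective <- function(W, G) {
    # ||X - X W G^T||_F^2 expressed through K = X^T X
    WG <- W %*% t(G)
    0.5 * (sum(diag(K)) - 2 * sum(K * t(WG)) + sum((t(WG) %*% K) * t(WG)))
  }
  run_restarts(opts, function(seed) {
    fac <- with_seed(seed, {
      W <- matrix(stats::runif(n * k), n, k)
      G <- matrix(stats::runif(n * k), n, k)
      list(W = sweep(W, 2, colSums(W), "/"), G = G)
    })
    W <- fac$W; G <- fac$G
    if (!is.null(opts$init$W)) W <- as.matrix(opts$init$W)
    if (!is.null(opts$init$Y)) G <- t(as.matrix(opts$init$Y))
    trace <- objective(W, G)
    converged <- FALSE
    for (iter in seq_len(opts$max_iter)) {
      GtG <- crossprod(G)
      W <- W * sqrt((Kp %*% G + Kn %*% W %*% GtG) /
                      guard_den(Kn %*% G + Kp %*% W %*% GtG))
      G <- G * sqrt((Kp %*% W + G %*% (t(W) %*% (Kn %*% W))) /
                      guard_den(Kn %*% W + G %*% (t(W) %*% (Kp %*% W))))
      # keep columns of W on the simplex without moving the product X W G^T
      d <- colSums(W)
      d[d == 0] <- 1
      W <- sweep(W, 2, d, "/")
      G <- sweep(G, 2, d, "*")
      f <- objective(W, G)
      trace <- c(trace, f)
      if (rel_change_small(trace[iter], f, opts$tol)) {
        converged <- TRUE
        break
      }
    }
    new_nmf_fit(A = matrix(NA_real_, 0, k), Y = t(G), k, trace, converged,
                "convex-core", extra = list(W = W))
  })
}

#' Orthogonal NMF (non-negative tri-factorization)
#'
#' Factorizes non-negative `X ~ A S Y` with all three factors non-negative,
#' pushing `A^T A` and `Y Y^T` towards the identity; the middle factor `S`
#' absorbs the magnitude freed by the normalization. The orthogonality is
#' enforced softly by the structure of the square-root multiplicative
#' updates; the realized deviations `||A^T A - I||_F` and `||Y Y^T - I||_F`
#' are reported in `extra$orth_dev_A` / `extra$orth_dev_Y` rather than being
#' constrained exactly.
#'
#' @inheritParams nmf_multiplicative
#' @return An `nmf_fit` with `extra$S` and the orthogonality deviations.
#' @export
orth_nmf <- function(data, k, opts = fit_options()) {
  data <- as_data_matrix(data)
  require_nonneg(data, "orth_nmf()")
  require_complete(data, "orth_nmf()")
  X <- data$X
  check_k(X, k, strict = FALSE)
  run_restarts(opts, function(seed) {
    fac <- init_factors(X, k, seed, opts$init, what = c("A", "Y", "S"))
    A <- fac$A; Y <- fac$Y; S <- fac$S
    objective <- function(A, S, Y) 0.5 * frob2(X - A %*% S %*% Y)
    trace <- objective(A, S, Y)
    converged <- FALSE
    for (iter in seq_len(opts$max_iter)) {
      # all update ingredients are non-negative for non-negative X
      G <- t(Y)                       # n x k
      XtAS <- t(X) %*% (A %*% S)
      G <- G * sqrt(XtAS / guard_den(G %*% crossprod(G, XtAS)))
      # S absorbs the magnitude: keep G on the orthonormal scale
      dg <- sqrt(colSums(G * G)); dg[dg == 0] <- 1
      G <- sweep(G, 2, dg, "/")
      S <- sweep(S, 2, dg, "*")
      Y <- t(G)
      XGS <- X %*% t(Y) %*% t(S)
      A <- A * sqrt(XGS / guard_den(A %*% crossprod(A, XGS)))
      da <- sqrt(colSums(A * A)); da[da == 0] <- 1
      A <- sweep(A, 2, da, "/")
      S <- sweep(S, 1, da, "*")
      S <- S * sqrt(crossprod(A, X %*% t(Y)) /
                      guard_den(crossprod(A) %*% S %*% tcrossprod(Y)))
      f <- objective(A, S, Y)
      trace <- c(trace, f)
      if (rel_change_small(trace[iter], f, opts$tol)) {
        converged <- TRUE
        break
      }
    }
    Ik <- diag(k)
    new_nmf_fit(A, Y, k, trace, converged, "orth-nmf",
                extra = list(S = S,
                             orth_dev_A = sqrt(frob2(crossprod(A) - Ik)),
                             orth_dev_Y = sqrt(frob2(tcrossprod(Y) - Ik))))
  })
}

#' Weighted NMF for data with missing values
#'
#' Optimizes `0.5 * ||M * (X - AY)||_F^2` where the binary mask `M` puts zero
#' weight on missing (`NaN`) cells, so only observed entries influence the
#' factors. The multiplicative rules are the masked form of the standard
#' ones; with a complete mask they reduce exactly to
#' [nmf_multiplicative()]. The product `A Y` provides an imputation of the
#' missing cells, returned as `extra$imputed`.
#'
#' @inheritParams nmf_multiplicative
#' @return An `nmf_fit` with `extra$imputed = A %*% Y`.
#' @export
weighted_nmf <- function(data, k, opts = fit_options()) {
  data <- as_data_matrix(data)
  require_nonneg(data, "weighted_nmf()")
  X <- data$X
  M <- data$mask
  check_k(X, k)
  if (any(rowSums(M) == 0) || any(colSums(M) == 0))
    warning("some rows or columns are fully missing; ",
            "their factor entries are unconstrained")
  X[M == 0] <- 0
  run_restarts(opts, function(seed) {
    fac <- init_factors(X, k, seed, opts$init)
    A <- fac$A; Y <- fac$Y
    objective <- function(A, Y) 0.5 * frob2(M * (X - A %*% Y))
    trace <- objective(A, Y)
    converged <- FALSE
    for (iter in seq_len(opts$max_iter)) {
      A <- A * ((M * X) %*% t(Y)) / guard_den((M * (A %*% Y)) %*% t(Y))
      Y <- Y * crossprod(A, M * X) / guard_den(crossprod(A, M * (A %*% Y)))
      f <- objective(A, Y)
      trace <- c(trace, f)
      if (rel_change_small(trace[iter], f, opts$tol)) {
        converged <- TRUE
        break
      }
    }
    new_nmf_fit(A, Y, k, trace, converged, "weighted-nmf",
                extra = list(imputed = A %*% Y))
  })
}

#' Omnibus factorization interface
#'
#' Dispatches to the named factorization variant; this is the entry point
#' used by the mining layer ([extract_features_train()], [bicluster()]) and
#' the command-line wrapper.
#'
#' @inheritParams nmf_multiplicative
#' @param method one of `"nmf"` (alternating NNLS, the default),
#'   `"nmf-mult"`, `"seminmf"`, `"seminmf-mult"`, `"sparse"`,
#'   `"sparse-kim-park"`, `"vsmf"`, `"vsmf-mult"`, `"convex"`, `"orth"`,
#'   `"weighted"`.
#' @param cfg a [vsmf_config()] for the penalized variants.
#' @return An `nmf_fit`.
#' @export
nmf <- function(data, k, method = "nmf", cfg = vsmf_config(),
                opts = fit_options()) {
  methods <- c("nmf", "nmf-mult", "seminmf", "seminmf-mult", "sparse",
               "sparse-kim-park", "vsmf", "vsmf-mult", "convex", "orth",
               "weighted")
  if (!method %in% methods)
    stop("unknown method \"", method, "\"; supported: ",
         paste(methods, collapse = ", "))
  switch(method,
    "nmf" = nmf_nnls(data, k, opts),
    "nmf-mult" = nmf_multiplicative(data, k, opts),
    "seminmf" = seminmf(data, k, "nnls", opts),
    "seminmf-mult" = seminmf(data, k, "mult", opts),
    "sparse" = sparse_nmf(data, k, cfg, "unit_norm", opts = opts),
    "sparse-kim-park" = sparse_nmf(data, k, cfg, "kim_park", opts = opts),
    "vsmf" = vsmf(data, k, cfg, "active_set", opts),
    "vsmf-mult" = vsmf(data, k, cfg, "mult", opts),
    "convex" = convex_nmf(data, k, opts),
    "orth" = orth_nmf(data, k, opts),
    "weighted" = weighted_nmf(data, k, opts))
}
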