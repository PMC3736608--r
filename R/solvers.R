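# Active-set solvers for non-negative quadratic programming (NNQP), its
# non-negative least-squares (NNLS) specialization, and an l1-regularized QP.
# These are the numerical engines behind every factorization variant and the
# NNLS classifier: each alternating step of an NMF reduces to one of them.

#' Solve a non-negative quadratic program column-wise
#'
#' Minimizes, independently for each column `g_i` of `G`,
#' \deqn{\min_{z \ge 0} \tfrac12 z^T H z + g_i^T z,}
#' the canonical non-negative quadratic program (NNQP). A Lawson-Hanson-style
#' active-set method is used: variables are partitioned into a zero (active)
#' set and a free (passive) set, the equality-constrained subproblem is solved
#' on the passive set, and the partition is revised until the
#' Karush-Kuhn-Tucker (KKT) conditions hold. The passive set found for one
#' column warm-starts the next, which pays off when neighbouring columns have
#' similar supports (as in alternating NMF updates).
#'
#' `H` must be symmetric positive semi-definite. A tiny ridge
#' (`1e-12 * trace(H)/p`) is added before solving so that rank-deficient Gram
#' matrices remain solvable without materially moving the optimum.
#'
#' @param H symmetric positive semi-definite matrix (p x p).
#' @param G matrix of linear terms, one problem per column (p x q); a vector
#'   is treated as a single column.
#' @param tol KKT tolerance: on return, `z >= 0`, the gradient `Hz + g` is
#'   `>= -tol` wherever `z = 0`, and the complementarity products
#'   `|z * (Hz + g)|` are `<= tol`.
#' @param max_iter maximum active-set iterations per column; defaults to
#'   `3 * p`. Hitting the cap raises a warning and returns the current
#'   iterate.
#' @param check validate symmetry and positive semi-definiteness of `H`.
#'   Internal callers that construct `H` as a Gram matrix disable this.
#'
#' @return An object of class `nnqp_solution`: list with `Z` (p x q solution,
#'   elementwise non-negative), `kkt_residual` (largest KKT violation over all
#'   columns) and `iterations` (per-column active-set iteration counts).
#' @seealso [solve_nnls()], [solve_l1qp()]
#' @export
#' @examples
#' sol <- solve_nnqp(diag(2), c(-1, 2))
#' sol$Z  # c(1, 0): positive part of -g under an identity Hessian
solve_nnqp <- function(H, G, tol = 1e-8, max_iter = NULL, check = TRUE) {
  H <- as.matrix(H)
  if (is.null(dim(G))) G <- matrix(G, ncol = 1L)
  G <- as.matrix(G)
  p <- nrow(H)
  if (ncol(H) != p)
    stop("H must be square, got ", p, " x ", ncol(H))
  if (nrow(G) != p)
    stop("G must have as many rows as H (", p, "), got ", nrow(G))
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0)
    stop("tol must be a positive scalar")
  if (check) {
    scale <- max(1, max(abs(H)))
    if (max(abs(H - t(H))) > 1e-10 * scale)
      stop("H is not symmetric (asymmetry exceeds 1e-10)")
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(1, max(ev)))
      stop("H is not positive semi-definite (eigenvalue ", min(ev), ")")
  }
  if (is.null(max_iter)) max_iter <- 3L * p

  q <- ncol(G)
  Z <- matrix(0, p, q)
  iters <- integer(q)
  kkt <- 0
  warm <- NULL
  for (i in seq_len(q)) {
    res <- nnqp_column(H, G[, i], tol, max_iter, warm)
    Z[, i] <- res$z
    iters[i] <- res$iterations
    kkt <- max(kkt, res$kkt)
    warm <- res$passive
  }
  dimnames(Z) <- list(rownames(H), colnames(G))
  structure(list(Z = Z, kkt_residual = kkt, iterations = iters),
            class = "nnqp_solution")
}

# Single-column Lawson-Hanson active-set iteration. `warm` is a logical
# passive-set guess; it is only adopted when its equality-constrained solution
# is strictly feasible, otherwise the cold start from z = 0 is used.
nnqp_column <- function(H, g, tol, max_iter, warm = NULL) {
  p <- length(g)
  z <- numeric(p)
  P <- logical(p)
  niter <- 0L

  # Equality-constrained solve on the passive set, with one step of
  # iterative refinement; rank-deficient subsystems fall back to a tiny
  # ridge (1e-12 * trace/p) that keeps the solver total.
  solve_passive <- function(P) {
    Hp <- H[P, P, drop = FALSE]
    gp <- g[P]
    z <- tryCatch(drop(solve(Hp, -gp)), error = function(e) NULL)
    if (is.null(z)) {
      ridge <- 1e-12 * max(sum(diag(Hp)), 1) / nrow(Hp)
      z <- tryCatch(drop(solve(Hp + diag(ridge, nrow(Hp)), -gp)),
                    error = function(e) NULL)
      if (is.null(z)) return(NULL)
    }
    r <- drop(Hp %*% z) + gp
    dz <- tryCatch(drop(solve(Hp, -r)), error = function(e) rep(0, length(z)))
    z + dz
  }

  if (!is.null(warm) && any(warm)) {
    zP <- solve_passive(warm)
    if (!is.null(zP) && all(zP > 0)) {
      P <- warm
      z[P] <- zP
    }
  }

  failed <- FALSE
  repeat {
    w <- drop(H %*% z) + g
    cand <- which(!P & w < -tol)
    if (!length(cand) || failed) break
    j <- cand[which.min(w[cand])]
    P[j] <- TRUE
    repeat {
      niter <- niter + 1L
      if (niter > max_iter) {
        warning("NNQP active-set solver hit the iteration cap (", max_iter,
                "); returning the current iterate")
        failed <- TRUE
        break
      }
      zP <- solve_passive(P)
      if (is.null(zP)) {
        # singular subsystem despite the ridge: back out the last addition
        P[j] <- FALSE
        break
      }
      idx <- which(P)
      if (all(zP > 0)) {
        z[] <- 0
        z[idx] <- zP
        break
      }
      neg <- which(zP <= 0)
      denom <- z[idx][neg] - zP[neg]
      ok <- denom > 0
      alpha <- if (any(ok)) min(z[idx][neg][ok] / denom[ok]) else 0
      z[idx] <- z[idx] + alpha * (zP - z[idx])
      drop_idx <- idx[zP <= 0 & z[idx] <= tol * max(1, max(abs(z)))]
      z[drop_idx] <- 0
      P[drop_idx] <- FALSE
      if (!any(P)) {
        z[] <- 0
        break
      }
    }
  }

  w <- drop(H %*% z) + g
  kkt <- max(0, if (any(z == 0)) max(-w[z == 0]) else 0, max(abs(z * w)))
  list(z = z, iterations = niter, kkt = kkt, passive = P)
}

#' Solve a non-negative least-squares problem
#'
#' Minimizes `0.5 * ||B - A Z||_F^2` over `Z >= 0`, column by column. NNLS is
#' the special case of NNQP with `H = A^T A` and `g_i = -A^T b_i`, and the
#' implementation delegates to [solve_nnqp()] on that Gram form. The Gram
#' matrices can also be supplied directly via `AtA` / `AtB`, which is how the
#' kernelized factorizations and the kernel NNLS classifier call the solver
#' without ever materializing `A`.
#'
#' @param A basis matrix (m x k); ignored when `AtA` and `AtB` are given.
#' @param B right-hand sides (m x q); a vector is one column.
#' @param AtA optional precomputed `A^T A` (k x k).
#' @param AtB optional precomputed `A^T B` (k x q).
#' @param tol KKT tolerance, as in [solve_nnqp()].
#'
#' @return An `nnqp_solution` whose `Z` is the k x q coefficient matrix.
#' @export
#' @examples
#' A <- cbind(c(1, 0), c(0, 2))
#' solve_nnls(A, c(2, 2))$Z  # decoupled coordinates: c(2, 1)
solve_nnls <- function(A = NULL, B = NULL, AtA = NULL, AtB = NULL,
                       tol = 1e-8) {
  if (is.null(AtA) || is.null(AtB)) {
    if (is.null(A) || is.null(B))
      stop("supply either (A, B) or precomputed (AtA, AtB)")
    A <- as.matrix(A)
    if (is.null(dim(B))) B <- matrix(B, ncol = 1L)
    B <- as.matrix(B)
    if (nrow(A) != nrow(B))
      stop("A and B must share their row (feature) dimension: ",
           nrow(A), " vs ", nrow(B))
    if (ncol(A) > nrow(A) || qr(A)$rank < ncol(A))
      warning("A is column rank-deficient; the NNLS solution may not be unique")
    AtA <- crossprod(A)
    AtB <- crossprod(A, B)
  }
  solve_nnqp(AtA, -as.matrix(AtB), tol = tol, check = FALSE)
}

#' Solve an l1-regularized quadratic program
#'
#' Minimizes `0.5 * z^T H z + g^T z + lambda1 * ||z||_1` over a sign-free
#' `z`. The variable is split as `z = u - v` with `u, v >= 0`, turning the
#' problem into an NNQP on the doubled system
#' `[H, -H; -H, H]` with linear term `[g + lambda1; -g + lambda1]`, which is
#' handed to [solve_nnqp()]. This is the update used by VSMF blocks on which
#' non-negativity is switched off but l1 sparsity is still wanted.
#'
#' @param H symmetric positive semi-definite matrix (p x p).
#' @param g linear term (length p).
#' @param lambda1 non-negative l1 weight; `0` reduces to an unconstrained QP.
#' @param tol KKT tolerance passed through to [solve_nnqp()].
#'
#' @return Numeric vector `z` of length p (may have either sign).
#' @export
#' @examples
#' solve_l1qp(matrix(1), -3, 1)  # scalar soft threshold: 3 - 1 = 2
solve_l1qp <- function(H, g, lambda1, tol = 1e-8) {
  if (!is.numeric(lambda1) || length(lambda1) != 1L || lambda1 < 0)
    stop("lambda1 must be a non-negative scalar")
  H <- as.matrix(H)
  g <- as.numeric(g)
  p <- nrow(H)
  H2 <- rbind(cbind(H, -H), cbind(-H, H))
  g2 <- c(g + lambda1, -g + lambda1)
  sol <- solve_nnqp(H2, g2, tol = tol, check = FALSE)
  drop(sol$Z[seq_len(p), 1] - sol$Z[p + seq_len(p), 1])
}

#' @export
print.nnqp_solution <- function(x, ...) {
  cat("NNQP solution:", nrow(x$Z), "variables x", ncol(x$Z), "columns\n")
  cat("  KKT residual:", format(x$kkt_residual), "\n")
  cat("  active-set iterations:", paste(range(x$iterations), collapse = "-"),
      "(min-max per column)\n")
  invisible(x)
}
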