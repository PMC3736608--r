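# Shared fixtures and independent oracles used across the suite.

# Exhaustive active-set oracle for small NNQP problems: enumerate every
# subset of free variables, solve the equality-constrained system, keep the
# feasible candidate with the lowest objective (including z = 0).
brute_force_nnqp <- function(H, g) {
  p <- length(g)
  best <- list(f = 0, z = numeric(p))
  for (s in seq_len(2^p - 1)) {
    S <- which(bitwAnd(s, 2^(seq_len(p) - 1)) > 0)
    zs <- tryCatch(solve(H[S, S, drop = FALSE], -g[S]),
                   error = function(e) NULL)
    if (is.null(zs) || any(zs < 0)) next
    z <- numeric(p)
    z[S] <- zs
    f <- 0.5 * sum(z * (H %*% z)) + sum(g * z)
    if (f < best$f - 1e-15) best <- list(f = f, z = z)
  }
  best$z
}

# Random PSD matrix with controlled conditioning (Wishart with a tall
# Gaussian factor).
random_psd <- function(p, df = 2 * p) {
  crossprod(matrix(rnorm(df * p), df, p))
}

# Largest KKT violation of a candidate NNQP solution.
kkt_violation <- function(H, g, z) {
  w <- drop(H %*% z) + g
  max(0,
      if (any(z == 0)) max(-w[z == 0]) else 0,
      max(abs(z * w)))
}

# Best label agreement over all permutations of cluster ids (k small).
permuted_agreement <- function(labels, truth) {
  k <- max(labels, truth)
  perms <- permutations_of(seq_len(k))
  best <- 0
  for (p in perms) best <- max(best, mean(p[labels] == truth))
  best
}

permutations_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in permutations_of(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# Best mean column correlation between two bases over factor permutations.
permuted_factor_correlation <- function(A_hat, A_true) {
  k <- ncol(A_true)
  best <- -1
  for (p in permutations_of(seq_len(k))) {
    r <- mean(vapply(seq_len(k), function(q)
      suppressWarnings(cor(A_hat[, p[q]], A_true[, q])), numeric(1)),
      na.rm = TRUE)
    best <- max(best, r)
  }
  best
}

# Identifiable planted factorization: factor-specific one-hot rows in A and
# hard cluster-indicator coefficients (exact zeros off-cluster), so the
# factors are pinned down up to permutation and scaling.
plant_identifiable_factors <- function(m, n, k, seed) {
  g <- generate_synthetic(m, n, k, seed = seed)
  Y <- matrix(0, k, n)
  set.seed(seed + 1)
  for (j in seq_len(n)) Y[g$labels[j], j] <- runif(1, 0.8, 1.2)
  list(X = g$A %*% Y, A = g$A, Y = Y, labels = g$labels)
}

relative_residual <- function(X, fit) {
  norm(X - fit$A %*% fit$Y, "F") / norm(X, "F")
}

# Objective trace monotone up to small relative slack.
trace_nonincreasing <- function(trace, slack = 1e-9) {
  if (length(trace) < 2) return(TRUE)
  d <- diff(trace)
  all(d <= slack * pmax(abs(trace[-length(trace)]), 1e-12))
}
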