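# NMF-based data mining: cluster assignment from the coefficient matrix,
# consensus/dispersion rank selection, biclustering, feature extraction into
# the metasample space, and entropy-based factor-specific feature selection.

#' Assign samples to clusters from an NMF coefficient matrix
#'
#' Sample `i` is assigned to the factor carrying its largest coefficient
#' (argmax over the rows of `y_i`); each basis vector acts as a cluster
#' prototype. Ties break to the lowest factor index; an all-zero column is
#' assigned to cluster 1 with a warning.
#'
#' @param Y non-negative coefficient matrix (k x n) or an `nmf_fit`.
#' @return An object of class `cluster_result`: list with integer `labels`
#'   (1..k), the `Y` used, and `k`.
#' @export
assign_clusters <- function(Y) {
  if (inherits(Y, "nmf_fit")) Y <- Y$Y
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("Y must be non-negative")
  zero <- colSums(Y) == 0
  if (any(zero))
    warning(sum(zero), " all-zero coefficient column(s) assigned to cluster 1")
  labels <- apply(Y, 2, which.max)
  structure(list(labels = as.integer(labels), Y = Y, k = nrow(Y)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("NMF clustering:", length(x$labels), "samples in", x$k, "clusters\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Consensus-based selection of the number of clusters
#'
#' For each candidate rank `k`, runs `runs` seeded factorizations, records
#' for every sample pair the fraction of runs in which they co-cluster
#' (the consensus matrix `C`), and scores the stability with the dispersion
#' coefficient
#' \deqn{\rho = \frac{1}{n^2}\sum_{ij} 4 (C_{ij} - \tfrac12)^2 \in [0, 1],}
#' which equals 1 exactly when `C` is binary (perfectly reproducible
#' clustering). The best `k` maximizes `rho`; since merging stable clusters
#' is itself stable, dispersion ties (within 1e-9) are resolved toward the
#' largest rank.
#'
#' @param data a [data_matrix()] or matrix.
#' @param k_range integer vector of candidate ranks.
#' @param runs number of factorization restarts per rank (>= 10 recommended).
#' @param method factorization passed to [nmf()].
#' @param opts [fit_options()]; run r uses seed `seed + 97 * r`.
#' @return List with `best_k` and `summaries`, one `consensus_summary`
#'   (fields `C`, `dispersion`, `runs`, `k`) per candidate rank.
#' @export
choose_best_k <- function(data, k_range, runs = 20L, method = "nmf",
                          opts = fit_options()) {
  if (!length(k_range)) stop("k_range must be non-empty")
  data <- as_data_matrix(data)
  n <- ncol(data$X)
  summaries <- lapply(k_range, function(k) {
    C <- matrix(0, n, n)
    for (r in seq_len(runs)) {
      opts_r <- opts
      opts_r$seed <- if (is.null(opts$seed)) NULL else opts$seed + 97L * r
      fit <- nmf(data, k, method = method, opts = opts_r)
      lab <- assign_clusters(fit$Y)$labels
      C <- C + outer(lab, lab, "==")
    }
    C <- C / runs
    structure(list(C = C, dispersion = dispersion_coefficient(C),
                   runs = runs, k = k),
              class = "consensus_summary")
  })
  names(summaries) <- paste0("k", k_range)
  disp <- vapply(summaries, `[[`, numeric(1), "dispersion")
  # a coarsening of a stable clustering is itself stable, so dispersion ties
  # are common below the true rank; resolve them toward the largest rank
  # (the finest clustering that is still fully reproducible)
  best <- max(which(disp >= max(disp) - 1e-9))
  list(best_k = k_range[best], summaries = summaries)
}

#' Dispersion coefficient of a consensus matrix
#'
#' @param C consensus matrix with entries in `[0, 1]`.
#' @return `rho = mean(4 * (C - 0.5)^2)`, in `[0, 1]`; 1 iff `C` is binary.
#' @export
dispersion_coefficient <- function(C) {
  C <- as.matrix(C)
  if (any(C < 0) || any(C > 1)) stop("consensus entries must lie in [0, 1]")
  mean(4 * (C - 0.5)^2)
}

#' NMF biclustering of features and samples
#'
#' Factorizes `X ~ A Y` and reads one bicluster per factor `q`: its samples
#' are those whose largest coefficient sits in row `q` (so the sample sets
#' partition the columns), and its features are those whose basis weight is
#' extreme for that factor, `A[i, q] >= mean(A[, q]) + row_z * sd(A[, q])`.
#'
#' @param data a [data_matrix()] or non-negative matrix.
#' @param k number of biclusters (factors).
#' @param row_z z-score threshold for feature membership (default 1).
#' @param method factorization passed to [nmf()].
#' @param opts [fit_options()].
#' @return List with `biclusters` (per factor: `factor_index`,
#'   `row_members`, `col_members`) and the underlying `fit`.
#' @export
bicluster <- function(data, k, row_z = 1, method = "nmf",
                      opts = fit_options()) {
  data <- as_data_matrix(data)
  fit <- nmf(data, k, method = method, opts = opts)
  labels <- assign_clusters(fit$Y)$labels
  bics <- lapply(seq_len(k), function(q) {
    a <- fit$A[, q]
    thr <- mean(a) + row_z * stats::sd(a)
    rows <- which(a >= thr)
    cols <- which(labels == q)
    if (!length(rows) || !length(cols))
      warning("bicluster ", q, " is empty (factor may be degenerate)")
    list(factor_index = q, row_members = rows, col_members = cols)
  })
  list(biclusters = bics, fit = fit)
}

#' Learn an NMF feature space from training data
#'
#' Factorizes the training matrix `X ~ A Y_tr`; the `k` columns of `A`
#' (metasamples) span the feature space and `Y_tr` holds the training
#' representations. The basis is kept so unknown samples can be projected
#' with [extract_features_test()]. For kernel methods
#' (`method = "kernel-seminmf"`), the training matrix and coefficient
#' pseudoinverse are stored instead of an explicit basis, and projection
#' uses inner products only.
#'
#' @param data a [data_matrix()] or matrix (features x samples).
#' @param k feature-space dimension.
#' @param method a linear method accepted by [nmf()], or
#'   `"kernel-seminmf"`.
#' @param cfg [vsmf_config()] for penalized variants.
#' @param spec [kernel_spec()] for the kernel path.
#' @param opts [fit_options()].
#' @return An object of class `feature_space` with `A`, `Y_tr`, `k`,
#'   `method` (and `X_tr`, `spec`, `pseudo` on the kernel path).
#' @export
extract_features_train <- function(data, k, method = "nmf",
                                   cfg = vsmf_config(),
                                   spec = kernel_spec("rbf"),
                                   opts = fit_options()) {
  data <- as_data_matrix(data)
  if (identical(method, "kernel-seminmf")) {
    K <- compute_kernel_matrix(data$X, data$X, spec)
    fit <- kernel_seminmf(K, k, opts = opts)
    return(structure(list(A = NULL, Y_tr = fit$Y, k = as.integer(k),
                          method = method, X_tr = data$X, spec = spec,
                          pseudo = fit$pseudo, fit = fit),
                     class = "feature_space"))
  }
  fit <- nmf(data, k, method = method, cfg = cfg, opts = opts)
  structure(list(A = fit$A, Y_tr = fit$Y, k = as.integer(k), method = method,
                 fit = fit),
            class = "feature_space")
}

#' Project unknown samples into a learned NMF feature space
#'
#' Solves the non-negative least squares problem `S ~ A Y_uk`, `Y_uk >= 0`,
#' mapping the `p` unknown samples onto the metasample basis learned by
#' [extract_features_train()]. On the kernel path only the inner products
#' `K(X_tr, S)` are used: the Gram form of the solve is
#' `H = (Y^+)^T K(X, X) Y^+` and `A^T S = (Y^+)^T K(X, S)`.
#'
#' @param space a `feature_space`.
#' @param S matrix of unknown samples (m x p).
#' @return The k x p coefficient matrix `Y_uk`.
#' @export
extract_features_test <- function(space, S) {
  S <- as.matrix(S)
  if (identical(space$method, "kernel-seminmf")) {
    if (nrow(S) != nrow(space$X_tr))
      stop("S must have ", nrow(space$X_tr), " features, got ", nrow(S))
    H <- t(space$pseudo) %*%
      compute_kernel_matrix(space$X_tr, space$X_tr, space$spec) %*%
      space$pseudo
    AtS <- t(space$pseudo) %*%
      compute_kernel_matrix(space$X_tr, S, space$spec)
    return(solve_nnls(AtA = (H + t(H)) / 2, AtB = AtS)$Z)
  }
  if (nrow(S) != nrow(space$A))
    stop("S must have ", nrow(space$A), " features, got ", nrow(S))
  solve_nnls(space$A, S)$Z
}

#' Entropy-based selection of factor-specific features
#'
#' Scores each feature by how concentrated its basis weights are on a single
#' factor. Rows of `A` are normalized to `p(i, q) = A[i, q] / sum_q A[i, q]`
#' and scored with
#' \deqn{score_i = 1 + \frac{1}{\log_2 k}\sum_q p(i,q) \log_2 p(i,q),}
#' i.e. one minus the normalized entropy: 1 for a perfectly factor-specific
#' (one-hot) row, 0 for a uniform row. Features scoring above
#' `mean(score) + threshold_sd * sd(score)` are selected and assigned to
#' their argmax factor. All-zero rows are excluded from the normalization and
#' reported separately.
#'
#' @param A non-negative basis matrix (m x k), `k >= 2`.
#' @param threshold_sd z-score selection threshold (default 2).
#' @return An object of class `entropy_selection`: `p` (row-normalized
#'   weights), `score`, `threshold`, `selected` (feature indices per
#'   factor), `zero_rows`.
#' @export
select_features_entropy <- function(A, threshold_sd = 2) {
  if (inherits(A, "nmf_fit")) A <- A$A
  A <- as.matrix(A)
  k <- ncol(A)
  if (k < 2) stop("entropy scoring needs at least two factors (k >= 2)")
  if (any(A < 0)) stop("A must be non-negative")
  rs <- rowSums(A)
  zero_rows <- which(rs == 0)
  p <- A / ifelse(rs == 0, 1, rs)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  score <- 1 + rowSums(plogp) / log2(k)
  score[zero_rows] <- NA_real_
  ok <- !is.na(score)
  thr <- mean(score[ok]) + threshold_sd * stats::sd(score[ok])
  sel_idx <- which(ok & score > thr)
  factor_of <- apply(A, 1, which.max)
  selected <- lapply(seq_len(k), function(q) sel_idx[factor_of[sel_idx] == q])
  structure(list(p = p, score = score, threshold = thr, selected = selected,
                 zero_rows = zero_rows, threshold_sd = threshold_sd),
            class = "entropy_selection")
}

#' @export
print.entropy_selection <- function(x, ...) {
  cat("entropy-based feature selection:",
      sum(lengths(x$selected)), "features selected at threshold",
      format(x$threshold), "\n")
  for (q in seq_along(x$selected))
    cat("  factor ", q, ": ", length(x$selected[[q]]), " features\n",
        sep = "")
  if (length(x$zero_rows))
    cat("  excluded all-zero rows:", length(x$zero_rows), "\n")
  invisible(x)
}
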