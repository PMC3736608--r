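# Support layer: planted-factor synthetic data, normalization and sparsity
# utilities, heat-map rendering, and gene-list output.

#' Generate a synthetic feature-by-sample matrix with planted NMF structure
#'
#' Builds a block-structured non-negative basis `A` (a block of
#' factor-specific one-hot rows per factor, on top of uniform background
#' rows), a cluster-indicator-plus-background coefficient matrix `Y`, and
#' returns `X = A Y` with optional additive Gaussian noise and uniformly
#' random missing entries. The construction mirrors the robustness protocols
#' used for the classifier experiments: noise variances in `[0, 4]` and
#' missing rates in `[0.1, 0.7]` are the meaningful ranges.
#'
#' Each sample in cluster `q` has coefficient `Y[q, ] ~ U(0.8, 1.2)` on its
#' own factor and small `U(0, 0.2)` background elsewhere, so clusters are
#' well separated at zero noise. Factor-specific rows of `A` carry a single
#' `U(1, 2)` weight; background rows are `U(0, 1)` across all factors.
#'
#' @param m,n,k features, samples, and true rank (`k <= min(m, n)`).
#' @param noise_variance variance of additive Gaussian noise (0 = exact).
#' @param missing_rate fraction of entries set to `NaN`, in `[0, 1)`;
#'   exactly `round(missing_rate * m * n)` entries are masked.
#' @param cluster_sizes sample count per cluster (defaults to an even
#'   split; must sum to `n`).
#' @param factor_specific_features one-hot row count per factor (default
#'   `round(0.1 * m)` each; their total must be `<= m`).
#' @param sign_mode `"non-negative"` clips noisy entries at zero;
#'   `"mixed"` keeps negative noise.
#' @param seed integer seed; the output is fully reproducible.
#' @return List with `data` (a [data_matrix()]), the planted `A`, `Y` and
#'   integer `labels` (cluster per sample).
#' @export
generate_synthetic <- function(m, n, k, noise_variance = 0,
                               missing_rate = 0, cluster_sizes = NULL,
                               factor_specific_features = NULL,
                               sign_mode = c("non-negative", "mixed"),
                               seed = 1L) {
  sign_mode <- match.arg(sign_mode)
  if (k > min(m, n)) stop("k must be <= min(m, n)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (is.null(cluster_sizes)) {
    cluster_sizes <- rep(n %/% k, k)
    cluster_sizes[seq_len(n %% k)] <- cluster_sizes[seq_len(n %% k)] + 1L
  }
  if (sum(cluster_sizes) != n) stop("cluster_sizes must sum to n")
  if (is.null(factor_specific_features))
    factor_specific_features <- rep(max(1L, round(0.1 * m / k)), k)
  if (sum(factor_specific_features) > m)
    stop("factor-specific features exceed the number of rows")

  with_seed(seed, {
    A <- matrix(0, m, k)
    row <- 1L
    for (q in seq_len(k)) {
      nf <- factor_specific_features[q]
      A[row:(row + nf - 1L), q] <- stats::runif(nf, 1, 2)
      row <- row + nf
    }
    if (row <= m)
      A[row:m, ] <- matrix(stats::runif((m - row + 1L) * k), ncol = k)
    labels <- rep(seq_len(k), cluster_sizes)
    Y <- matrix(stats::runif(k * n, 0, 0.2), k, n)
    for (j in seq_len(n)) Y[labels[j], j] <- stats::runif(1, 0.8, 1.2)
    X <- A %*% Y
    if (noise_variance > 0) {
      X <- X + matrix(stats::rnorm(m * n, sd = sqrt(noise_variance)), m, n)
      if (sign_mode == "non-negative") X[X < 0] <- 0
    }
    if (missing_rate > 0) {
      idx <- sample.int(m * n, round(missing_rate * m * n))
      X[idx] <- NaN
    }
    rownames(X) <- paste0("feature", seq_len(m))
    colnames(X) <- paste0("sample", seq_len(n))
    list(data = data_matrix(X, sign_mode), A = A, Y = Y,
         labels = labels)
  })
}

#' Standardize rows or columns to mean 0 and standard deviation 1
#'
#' Uses the sample convention (denominator `length - 1`). Constant vectors
#' along the chosen axis become all-zero with a warning.
#'
#' @param X numeric matrix.
#' @param axis `"features"` (rows, the default) or `"samples"` (columns).
#' @return The standardized matrix.
#' @export
normalize_mean0_std1 <- function(X, axis = c("features", "samples")) {
  axis <- match.arg(axis)
  X <- as.matrix(X)
  if (axis == "samples") return(t(normalize_mean0_std1(t(X), "features")))
  mu <- rowMeans(X)
  sd <- apply(X, 1, stats::sd)
  const <- sd == 0
  if (any(const)) {
    warning(sum(const), " constant row(s) mapped to zero")
    sd[const] <- 1
  }
  out <- (X - mu) / sd
  out[const, ] <- 0
  out
}

#' Fraction of (near-)zero entries of a matrix
#'
#' @param M numeric matrix.
#' @param zero_tol entries with `|entry| <= zero_tol` count as zero. The
#'   default 0 counts exact zeros, which matches the active-set variants;
#'   multiplicative-rule outputs only approach zero, so pass a small
#'   positive tolerance to measure their sparsity.
#' @return Sparsity in `[0, 1]`.
#' @export
matrix_sparsity <- function(M, zero_tol = 0) {
  M <- as.matrix(M)
  if (!length(M)) stop("cannot compute the sparsity of an empty matrix")
  if (zero_tol < 0) stop("zero_tol must be >= 0")
  mean(abs(M) <= zero_tol)
}

#' Three-panel NMF heat map (data, basis, coefficients)
#'
#' Writes an image with the data matrix, the basis `A` and the coefficients
#' `Y` side by side, columns reordered by cluster assignment. In
#' `"biclustering"` mode the feature rows are additionally reordered by
#' their argmax factor so factor-specific blocks are contiguous.
#'
#' @param X data matrix or [data_matrix()].
#' @param fit an `nmf_fit`.
#' @param labels optional known sample labels, drawn as a side strip.
#' @param path output image path (`.svg`, `.pdf` or `.png`).
#' @param mode `"clustering"` (reorder samples) or `"biclustering"`
#'   (reorder samples and features).
#' @return Invisibly, a list with the `row_order` and `col_order` used.
#' @export
render_heatmap <- function(X, fit, labels = NULL, path,
                           mode = c("clustering", "biclustering")) {
  mode <- match.arg(mode)
  X <- if (inherits(X, "data_matrix")) X$X else as.matrix(X)
  stopifnot(nrow(X) == nrow(fit$A), ncol(X) == ncol(fit$Y))
  col_order <- order(assign_clusters(fit$Y)$labels)
  row_order <- if (mode == "biclustering")
    order(apply(fit$A, 1, which.max)) else seq_len(nrow(X))

  open_device(path, width = 9, height = 4)
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(1:3, 1), widths = c(3, 1.2, 2))
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  draw <- function(M, main) {
    graphics::par(mar = c(2, 2, 3, 1))
    graphics::image(t(M[rev(seq_len(nrow(M))), , drop = FALSE]),
                    col = pal, axes = FALSE, main = main)
    graphics::box()
  }
  Xs <- X[row_order, col_order, drop = FALSE]
  Xs[is.na(Xs)] <- 0
  draw(Xs, "data")
  draw(fit$A[row_order, , drop = FALSE], "basis A")
  draw(fit$Y[, col_order, drop = FALSE], "coefficients Y")
  invisible(list(row_order = row_order, col_order = col_order))
}

#' Write a feature (gene) list to a text file
#'
#' One feature name per line, with an optional tab-separated score column;
#' the file round-trips through [read_gene_list()].
#'
#' @param names character vector of feature names (non-empty).
#' @param scores optional numeric scores, same length.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_gene_list <- function(names, scores = NULL, path) {
  if (!length(names)) stop("the feature list is empty")
  lines <- if (is.null(scores)) as.character(names)
           else paste(names, format(scores, digits = 15), sep = "\t")
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' @rdname write_gene_list
#' @return `read_gene_list()`: data.frame with `name` and (if present)
#'   `score`.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (all(lengths(parts) >= 2))
    data.frame(name = vapply(parts, `[[`, "", 1),
               score = as.numeric(vapply(parts, `[[`, "", 2)))
  else
    data.frame(name = lines)
}

#' Read and write feature-by-sample matrices as delimited text
#'
#' The format is a header row of sample identifiers, a first column of
#' feature identifiers, and tab- (`.tsv`, default) or comma- (`.csv`)
#' separated numeric values; `NaN`/`NA` encode missing entries.
#'
#' @param path file path; the delimiter follows the extension.
#' @return `read_matrix_delim()`: a numeric matrix with dimnames.
#' @export
read_matrix_delim <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, comment.char = "",
                          quote = "\"")
  as.matrix(df)
}

#' @rdname read_matrix_delim
#' @param X numeric matrix (dimnames optional).
#' @export
write_matrix_delim <- function(X, path) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("feature", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("sample", seq_len(ncol(X)))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-label table
#'
#' Expects two delimited columns, `sample_id` and `class`, with a header.
#'
#' @param path file path (tab- or comma-separated by extension).
#' @return Named vector of labels, names = sample ids.
#' @export
read_labels_delim <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "")
  stats::setNames(df[[2]], df[[1]])
}
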