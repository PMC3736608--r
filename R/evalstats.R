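# Statistical comparison of classifiers: permutation test for the minimum
# significant training size, inverse-power-law learning curves, the Friedman
# rank test with the post-hoc Nemenyi critical difference, and the CD
# diagram.

#' Smallest training size with significantly better-than-chance accuracy
#'
#' For each candidate size `n`, repeatedly samples `n` training points
#' (stratified), evaluates the classifier on the remaining samples, and
#' compares the observed mean accuracy against a label-permutation null:
#' the labels are shuffled and the identical protocol re-run `n_perm`
#' times. The permutation p-value is
#' `(1 + #{null >= observed}) / (n_perm + 1)`; the smallest candidate size
#' with `p < alpha` is returned (`NA` if none reaches significance).
#'
#' @param X data matrix (m features x n samples).
#' @param labels class labels.
#' @param candidate_sizes ascending training sizes to test.
#' @param alpha significance level in (0, 1).
#' @param reps replicates used for the observed accuracy at each size.
#' @param n_perm label permutations for the null (>= 200 recommended).
#' @param classifier as in [cross_validate()].
#' @param seed integer seed.
#' @return List with `min_size` (smallest significant size or `NA`) and a
#'   data.frame `table` of size, observed accuracy and p-value.
#' @export
minimum_significant_size <- function(X, labels, candidate_sizes,
                                     alpha = 0.05, reps = 10L,
                                     n_perm = 200L, classifier = "nnls",
                                     seed = 1L) {
  X <- as.matrix(X)
  n <- ncol(X)
  if (any(candidate_sizes >= n))
    stop("candidate sizes must leave at least one held-out sample")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  clf <- resolve_classifier(classifier, kernel_spec("linear"), 0,
                            "min_class_residual")

  eval_once <- function(lab, size, s) {
    tr <- with_seed(s, stratified_sample(lab, size))
    pred <- tryCatch(
      clf(X[, tr, drop = FALSE], lab[tr], X[, -tr, drop = FALSE]),
      error = function(e) NULL)
    if (is.null(pred)) return(NA_real_)
    mean(pred == lab[-tr])
  }

  rows <- NULL
  min_size <- NA_integer_
  for (i in seq_along(candidate_sizes)) {
    size <- candidate_sizes[i]
    obs <- mean(vapply(seq_len(reps), function(r)
      eval_once(labels, size, seed + 13L * i + r), numeric(1)),
      na.rm = TRUE)
    null_acc <- vapply(seq_len(n_perm), function(b) {
      lab_b <- with_seed(seed + 7919L * b + i, sample(labels))
      eval_once(lab_b, size, seed + 7919L * b + 31L * i)
    }, numeric(1))
    p <- (1 + sum(null_acc >= obs, na.rm = TRUE)) /
      (sum(!is.na(null_acc)) + 1)
    rows <- rbind(rows, data.frame(size = size, accuracy = obs, p_value = p))
    if (is.na(min_size) && p < alpha) min_size <- as.integer(size)
  }
  list(min_size = min_size, table = rows, alpha = alpha)
}

# Stratified sample of `size` indices: allocates proportionally across
# classes (each class gets at least one slot while slots remain).
stratified_sample <- function(labels, size) {
  classes <- unique(labels)
  if (size < length(classes)) {
    # too few slots for stratification: plain random sample
    return(sample.int(length(labels), size))
  }
  counts <- table(labels)[as.character(classes)]
  alloc <- pmax(1, round(size * as.numeric(counts) / length(labels)))
  while (sum(alloc) > size) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1
  while (sum(alloc) < size) alloc[which.min(alloc)] <- alloc[which.min(alloc)] + 1
  idx <- unlist(lapply(seq_along(classes), function(ci) {
    pool <- which(labels == classes[ci])
    sample(pool, min(alloc[ci], length(pool)))
  }))
  if (length(idx) < size) {
    extra <- setdiff(seq_along(labels), idx)
    idx <- c(idx, sample(extra, size - length(idx)))
  }
  idx
}

#' Fit an inverse-power-law learning curve
#'
#' Fits mean error rates at increasing training sizes with
#' \deqn{e(n) = a \, n^{-\alpha} + b,}
#' where `b` is the asymptotic error reached with unlimited data, `a > 0`
#' the amplitude and `alpha > 0` the decay exponent. Initial values come
#' from a log-log regression of `errors - min(errors) + eps` on `n`; the
#' bounded Levenberg-Marquardt fit (`a >= 0`, `alpha` in (0, 3],
#' `b` in [0, 1)) then minimizes the (optionally weighted) residual sum of
#' squares.
#'
#' @param sizes training sizes (>= 3 distinct values).
#' @param errors mean error rates in `[0, 1]`, one per size.
#' @param weights optional non-negative fitting weights.
#' @return An object of class `learning_curve` with `a`, `alpha`, `b`,
#'   `sizes`, `errors`, `rss` and a `predict()` method.
#' @export
fit_learning_curve <- function(sizes, errors, weights = NULL) {
  sizes <- as.numeric(sizes); errors <- as.numeric(errors)
  if (length(unique(sizes)) < 3)
    stop("need at least 3 distinct training sizes")
  if (length(sizes) != length(errors))
    stop("sizes and errors must have equal length")
  if (any(errors < 0 | errors > 1)) stop("error rates must lie in [0, 1]")
  if (is.null(weights)) weights <- rep(1, length(sizes))

  if (stats::sd(errors) < 1e-12) {
    # flat curve: no decay component is identifiable
    return(new_learning_curve(0, 1, mean(errors), sizes, errors, 0))
  }
  eps <- 1e-6
  b0 <- max(0, min(errors) * 0.9)
  ll <- stats::lm(log(pmax(errors - b0, eps)) ~ log(sizes))
  alpha0 <- min(max(-stats::coef(ll)[2], 0.01), 3)
  a0 <- min(max(exp(stats::coef(ll)[1]), 1e-6), 1e3)
  fit <- tryCatch(
    minpack.lm::nlsLM(errors ~ a * sizes^(-alpha) + b,
                      start = list(a = a0, alpha = alpha0, b = b0),
                      lower = c(a = 0, alpha = 1e-6, b = 0),
                      upper = c(a = Inf, alpha = 3, b = 1 - 1e-9),
                      weights = weights,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    obj <- function(par)
      sum(weights * (errors - par[1] * sizes^(-par[2]) - par[3])^2)
    op <- stats::optim(c(a0, alpha0, b0), obj, method = "L-BFGS-B",
                       lower = c(0, 1e-6, 0), upper = c(Inf, 3, 1 - 1e-9))
    par <- op$par
    return(new_learning_curve(par[1], par[2], par[3], sizes, errors,
                              op$value))
  }
  cf <- stats::coef(fit)
  new_learning_curve(cf["a"], cf["alpha"], cf["b"], sizes, errors,
                     sum(weights * stats::resid(fit)^2))
}

new_learning_curve <- function(a, alpha, b, sizes, errors, rss) {
  structure(list(a = unname(a), alpha = unname(alpha), b = unname(b),
                 sizes = sizes, errors = errors, rss = unname(rss)),
            class = "learning_curve")
}

#' @export
predict.learning_curve <- function(object, newdata = object$sizes, ...) {
  n <- if (is.list(newdata)) newdata$sizes else as.numeric(newdata)
  object$a * n^(-object$alpha) + object$b
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("learning curve e(n) = %.4g * n^(-%.4g) + %.4g  (rss %.3g)\n",
              x$a, x$alpha, x$b, x$rss))
  invisible(x)
}

#' Friedman rank test over a classifiers-by-datasets accuracy table
#'
#' Ranks the classifiers within each dataset (rank 1 = highest accuracy,
#' ties averaged) and computes the Friedman statistic
#' \deqn{\chi^2_F = \frac{12N}{k(k+1)}\left[\sum_j R_j^2 -
#'   \frac{k(k+1)^2}{4}\right]}
#' with `R_j` the mean rank of classifier `j` over the `N` datasets, tested
#' against a chi-square with `k - 1` degrees of freedom. The less
#' conservative Iman-Davenport F transformation and the Nemenyi critical
#' difference at level `alpha` are also reported.
#'
#' @param accuracies numeric matrix, classifiers in rows, datasets in
#'   columns; no missing cells.
#' @param alpha significance level for the critical difference.
#' @return An object of class `comparison_table`: `accuracies`, `ranks`,
#'   `mean_ranks`, `chi2_F`, `p_value`, `iman_davenport_F`, `p_value_iman`,
#'   `CD`, `alpha`, `k`, `N`.
#' @export
friedman_test <- function(accuracies, alpha = 0.05) {
  A <- as.matrix(accuracies)
  if (anyNA(A)) stop("the accuracy table must be complete (no NA cells)")
  k <- nrow(A); N <- ncol(A)
  if (k < 2 || N < 2) stop("need at least 2 classifiers and 2 datasets")
  ranks <- apply(A, 2, function(col) rank(-col, ties.method = "average"))
  R <- rowMeans(ranks)
  chi2 <- 12 * N / (k * (k + 1)) * (sum(R^2) - k * (k + 1)^2 / 4)
  p <- stats::pchisq(chi2, df = k - 1, lower.tail = FALSE)
  denom <- N * (k - 1) - chi2
  FF <- if (denom > 0) (N - 1) * chi2 / denom else Inf
  pF <- stats::pf(FF, k - 1, (k - 1) * (N - 1), lower.tail = FALSE)
  structure(list(accuracies = A, ranks = ranks, mean_ranks = R,
                 chi2_F = chi2, p_value = p, iman_davenport_F = FF,
                 p_value_iman = pF, CD = nemenyi_cd(k, N, alpha),
                 alpha = alpha, k = k, N = N),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("Friedman test:", x$k, "classifiers x", x$N, "datasets\n")
  cat(sprintf("  chi2_F = %.4f (p = %.4g), Iman-Davenport F = %.4f (p = %.4g)\n",
              x$chi2_F, x$p_value, x$iman_davenport_F, x$p_value_iman))
  cat(sprintf("  Nemenyi CD at alpha = %g: %.4f\n", x$alpha, x$CD))
  mr <- sort(x$mean_ranks)
  nm <- names(mr)
  if (is.null(nm)) nm <- paste0("classifier", order(x$mean_ranks))
  cat("  mean ranks:",
      paste(sprintf("%s = %.2f", nm, mr), collapse = ", "), "\n")
  invisible(x)
}

#' Nemenyi critical difference
#'
#' Two classifiers differ significantly when their mean ranks differ by more
#' than
#' \deqn{CD = q_\alpha(k) \sqrt{\frac{k(k+1)}{6N}},}
#' where `q_alpha(k)` is the studentized range quantile (infinite degrees of
#' freedom) divided by `sqrt(2)`, computed numerically via [stats::qtukey()]
#' rather than read off a table. At `k = 2` it reduces to the normal
#' quantile (1.960 at `alpha = 0.05`).
#'
#' @param k number of classifiers (2..20).
#' @param N number of datasets.
#' @param alpha significance level in (0, 1).
#' @return The critical difference (scalar, rank units).
#' @export
nemenyi_cd <- function(k, N, alpha = 0.05) {
  if (k < 2 || k > 20) stop("k must lie in 2..20")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a scalar in (0, 1)")
  q <- stats::qtukey(1 - alpha, nmeans = k, df = Inf) / sqrt(2)
  q * sqrt(k * (k + 1) / (6 * N))
}

#' Group classifiers not separated by the critical difference
#'
#' Computes the maximal groups of classifiers whose mean ranks span at most
#' `CD` (the horizontal bars of a critical-difference diagram).
#'
#' @param mean_ranks named vector of mean ranks.
#' @param CD critical difference.
#' @return List of integer vectors (indices into `mean_ranks`, sorted by
#'   rank), one per maximal group of size >= 2.
#' @export
cd_groups <- function(mean_ranks, CD) {
  ord <- order(mean_ranks)
  r <- mean_ranks[ord]
  k <- length(r)
  groups <- list()
  for (i in seq_len(k)) {
    j <- max(which(r - r[i] <= CD + 1e-12))
    if (j > i) groups[[length(groups) + 1L]] <- ord[i:j]
  }
  # drop groups nested inside another
  keep <- vapply(seq_along(groups), function(g)
    !any(vapply(seq_along(groups), function(h)
      h != g && all(groups[[g]] %in% groups[[h]]), logical(1))),
    logical(1))
  groups[keep]
}

#' Draw a critical-difference diagram
#'
#' Places the classifiers at their mean ranks on a 1..k axis, draws the CD
#' ruler, and connects groups of classifiers whose mean ranks are not
#' separated by more than the critical difference.
#'
#' @param table a `comparison_table` from [friedman_test()].
#' @param path output image path; the device is chosen by extension
#'   (`.svg`, `.pdf` or `.png`).
#' @return Invisibly, the group structure from [cd_groups()].
#' @export
render_cd_diagram <- function(table, path) {
  groups <- cd_groups(table$mean_ranks, table$CD)
  open_device(path, width = 7, height = 3.5)
  on.exit(grDevices::dev.off())
  R <- table$mean_ranks
  k <- table$k
  nm <- names(R)
  if (is.null(nm)) nm <- paste0("clf", seq_len(k))
  graphics::par(mar = c(2, 1, 3, 1))
  ylim_low <- -(length(groups) + 2)
  graphics::plot(NULL, xlim = c(0.5, k + 0.5), ylim = c(ylim_low, 4),
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(3, at = seq_len(k))
  graphics::mtext("mean rank", side = 3, line = 2)
  # CD ruler
  graphics::segments(1, 3, 1 + table$CD, 3, lwd = 2)
  graphics::text((2 + table$CD) / 2, 3.5,
                 sprintf("CD = %.3f", table$CD), cex = 0.8)
  ord <- order(R)
  for (pos in seq_len(k)) {
    i <- ord[pos]
    y_lab <- if (pos %% 2 == 1) 1.2 else 2.2
    graphics::segments(R[i], 0, R[i], y_lab - 0.3)
    graphics::text(R[i], y_lab, nm[i], cex = 0.8)
  }
  graphics::abline(h = 0)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    graphics::segments(min(R[idx]) - 0.05, -g, max(R[idx]) + 0.05, -g,
                       lwd = 3)
  }
  invisible(groups)
}

open_device <- function(path, width, height) {
  ext <- tolower(sub(".*\\.", "", basename(path)))
  switch(ext,
    svg = grDevices::svg(path, width = width, height = height),
    pdf = grDevices::pdf(path, width = width, height = height),
    png = grDevices::png(path, width = width * 100, height = height * 100),
    stop("unsupported image extension: ", ext))
}
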