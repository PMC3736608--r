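# The NNLS sparse-representation classifier: every unknown sample is modeled
# as a sparse non-negative combination of the *training samples themselves*
# (no factors are learned), so fitting stores a Gram matrix and prediction is
# one NNQP solve per sample. Because only inner products enter, the
# classifier kernelizes directly and tolerates missing values through
# pairwise common-support inner products.

#' Missing-value-aware Gram matrix
#'
#' Entry `(i, j)` is the inner product of columns `x_i` and `x_j` restricted
#' to the features observed in *both* samples, after each restricted vector
#' is rescaled to unit l2 norm on that common support. No imputation is
#' performed; missing cells are simply ignored. With complete data this is
#' the Gram matrix of the column-normalized samples, so all diagonal entries
#' of `missing_aware_gram(X, X)` equal 1.
#'
#' @param X1 matrix (m x p), `NaN`/`NA` marking missing entries.
#' @param X2 matrix (m x q); defaults to `X1`.
#' @return The p x q matrix of common-support normalized inner products.
#'   A sample pair with no common observed feature is an error.
#' @export
missing_aware_gram <- function(X1, X2 = X1) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (nrow(X1) != nrow(X2))
    stop("X1 and X2 must share the feature dimension")
  O1 <- !is.na(X1); O2 <- !is.na(X2)
  if (all(O1) && all(O2)) {
    n1 <- sqrt(colSums(X1^2)); n1[n1 == 0] <- 1
    n2 <- sqrt(colSums(X2^2)); n2[n2 == 0] <- 1
    return(crossprod(sweep(X1, 2, n1, "/"), sweep(X2, 2, n2, "/")))
  }
  p <- ncol(X1); q <- ncol(X2)
  G <- matrix(0, p, q)
  for (i in seq_len(p)) {
    for (j in seq_len(q)) {
      common <- O1[, i] & O2[, j]
      if (!any(common))
        stop("samples ", i, " and ", j, " have disjoint observed support; ",
             "their inner product is undefined")
      a <- X1[common, i]; b <- X2[common, j]
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      G[i, j] <- if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
    }
  }
  G
}

# Nearest PSD projection: clip negative eigenvalues to zero.
psd_project <- function(K) {
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) >= 0) return(K)
  v <- pmax(eg$values, 0)
  K2 <- eg$vectors %*% (v * t(eg$vectors))
  (K2 + t(K2)) / 2
}

#' Remap class labels to 0..C-1
#'
#' @param labels vector of class labels (any atomic type).
#' @return List with `y` (integer labels 0..C-1, ordered by the sorted
#'   unique input values) and `levels` (the original values).
#' @export
change_class_labels <- function(labels) {
  lev <- sort(unique(labels))
  if (length(lev) < 2) stop("at least two classes are required")
  list(y = as.integer(match(labels, lev)) - 1L, levels = lev)
}

#' Fit the NNLS sparse-representation classifier
#'
#' Training stores the samples (they *are* the basis vectors), the remapped
#' labels and the training Gram matrix: the missing-aware common-support
#' Gram for linear kernels (which also covers complete data), or the chosen
#' kernel matrix when `spec` is non-linear and the data are complete.
#'
#' @param X_tr training matrix (m features x n samples), `NaN` for missing.
#' @param labels class label per training sample (>= 2 classes).
#' @param spec a [kernel_spec()]; default linear.
#' @param lambda_sparse non-negative l1 weight on the representation
#'   coefficients (sparsity regularization against overfitting).
#' @param decision_rule `"min_class_residual"` (assign the class whose
#'   training samples reconstruct the unknown with smallest residual) or
#'   `"max_class_coefficient"` (assign the class with the largest total
#'   coefficient mass).
#' @return An object of class `nnls_classifier`.
#' @export
nnls_fit <- function(X_tr, labels, spec = kernel_spec("linear"),
                     lambda_sparse = 0,
                     decision_rule = c("min_class_residual",
                                       "max_class_coefficient")) {
  decision_rule <- match.arg(decision_rule)
  X_tr <- as.matrix(X_tr)
  if (length(labels) != ncol(X_tr))
    stop("need one label per training sample")
  if (lambda_sparse < 0) stop("lambda_sparse must be >= 0")
  lab <- change_class_labels(labels)
  has_missing <- anyNA(X_tr)
  if (spec$name == "linear" || has_missing) {
    if (spec$name != "linear" && has_missing)
      stop("kernel NNLS classification requires complete data")
    gram <- missing_aware_gram(X_tr, X_tr)
  } else {
    gram <- compute_kernel_matrix(X_tr, X_tr, spec)
  }
  # pairwise common-support inner products need not form a PSD matrix;
  # project to the nearest PSD matrix so the NNQP solve is well posed
  structure(list(X_tr = X_tr, y = lab$y, levels = lab$levels, spec = spec,
                 lambda_sparse = lambda_sparse,
                 decision_rule = decision_rule,
                 gram = psd_project((gram + t(gram)) / 2)),
            class = "nnls_classifier")
}

#' @export
print.nnls_classifier <- function(x, ...) {
  cat("NNLS classifier:", ncol(x$X_tr), "training samples,",
      length(x$levels), "classes,", x$spec$name, "kernel\n")
  cat("  lambda =", x$lambda_sparse, "| rule =", x$decision_rule, "\n")
  invisible(x)
}

#' Predict with the NNLS classifier
#'
#' Each unknown sample `s` is represented as a sparse non-negative
#' combination of the training samples by solving
#' `min_{y >= 0} 0.5 ||s - X_tr y||^2 + lambda ||y||_1` in Gram form
#' (`H` = training Gram, `g = lambda - K(X_tr, s)`), so only inner products
#' are needed. Under `"min_class_residual"` the predicted class minimizes
#' the reconstruction residual using that class's coefficients alone,
#' `||s - X_tr y_c||^2 = k(s,s) - 2 y_c^T g_s + y_c^T H y_c`; under
#' `"max_class_coefficient"` it maximizes the class's coefficient sum. Ties
#' break to the lowest class id.
#'
#' @param model an `nnls_classifier` from [nnls_fit()].
#' @param S unknown samples (m x p), `NaN` for missing.
#' @return List with `labels` (in the original label space), `class_ids`
#'   (0..C-1), and the coefficient matrix `coefficients` (n_train x p).
#' @export
nnls_predict <- function(model, S) {
  S <- as.matrix(S)
  if (nrow(S) != nrow(model$X_tr))
    stop("S must have ", nrow(model$X_tr), " features")
  if (model$spec$name == "linear" || anyNA(S) || anyNA(model$X_tr)) {
    if (model$spec$name != "linear")
      stop("kernel NNLS classification requires complete data")
    Gs <- missing_aware_gram(model$X_tr, S)
    kss <- rep(1, ncol(S))   # unit self-norm on own support
  } else {
    Gs <- compute_kernel_matrix(model$X_tr, S, model$spec)
    kss <- vapply(seq_len(ncol(S)), function(j)
      compute_kernel_matrix(S[, j, drop = FALSE], S[, j, drop = FALSE],
                            model$spec)[1, 1], numeric(1))
  }
  H <- model$gram
  coef <- solve_nnqp(H, model$lambda_sparse - Gs, check = FALSE)$Z
  classes <- sort(unique(model$y))
  pred <- integer(ncol(S))
  for (j in seq_len(ncol(S))) {
    y <- coef[, j]
    crit <- vapply(classes, function(c) {
      yc <- y * (model$y == c)
      if (model$decision_rule == "min_class_residual")
        kss[j] - 2 * sum(yc * Gs[, j]) + drop(crossprod(yc, H %*% yc))
      else
        -sum(yc)
    }, numeric(1))
    pred[j] <- classes[which.min(crit)]
  }
  list(labels = model$levels[pred + 1L], class_ids = pred,
       coefficients = coef)
}

#' One-nearest-neighbor baseline classifier
#'
#' Euclidean 1-NN used as the reference point in the robustness
#' experiments.
#'
#' @param X_tr training matrix (m x n), complete.
#' @param labels training labels.
#' @param S test samples (m x p).
#' @return Predicted labels for the columns of `S`.
#' @export
nearest_neighbor_classify <- function(X_tr, labels, S) {
  X_tr <- as.matrix(X_tr); S <- as.matrix(S)
  d2 <- outer(colSums(S * S), colSums(X_tr * X_tr), "+") -
    2 * crossprod(S, X_tr)
  labels[apply(d2, 1, which.min)]
}

# Resolve a classifier argument ("nnls", "1nn", or a function
# (X_tr, labels, S) -> predicted labels) into a function.
resolve_classifier <- function(classifier, spec, lambda_sparse,
                               decision_rule) {
  if (is.function(classifier)) return(classifier)
  switch(match.arg(classifier, c("nnls", "1nn")),
    nnls = function(X_tr, labels, S) {
      model <- nnls_fit(X_tr, labels, spec = spec,
                        lambda_sparse = lambda_sparse,
                        decision_rule = decision_rule)
      nnls_predict(model, S)$labels
    },
    "1nn" = nearest_neighbor_classify)
}

# Stratified fold assignment; degrades to plain k-fold (with a warning) when
# some class has fewer members than folds.
stratified_folds <- function(labels, folds) {
  n <- length(labels)
  fold_id <- integer(n)
  if (min(table(labels)) < folds) {
    warning("a class has fewer members than folds; ",
            "using plain (unstratified) k-fold")
    fold_id[sample.int(n)] <- rep_len(seq_len(folds), n)
    return(fold_id)
  }
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' Repeated stratified k-fold cross-validation
#'
#' Repeats stratified k-fold cross-validation `runs` times (run r reseeds
#' the fold split with `seed + r - 1`) and collects per-fold accuracies.
#'
#' @param X data matrix (m features x n samples), `NaN` for missing when the
#'   classifier supports it.
#' @param labels class label per sample.
#' @param folds number of folds (>= 2).
#' @param runs number of repetitions.
#' @param classifier `"nnls"`, `"1nn"`, or a function
#'   `(X_tr, labels_tr, S) -> predicted labels`.
#' @param spec,lambda_sparse,decision_rule NNLS classifier configuration.
#' @param seed integer seed driving all fold splits.
#' @return An object of class `cv_result`: `fold_accuracies`
#'   (runs x folds matrix), `mean_accuracy`, `std_accuracy`, `config`.
#' @export
cross_validate <- function(X, labels, folds = 4L, runs = 1L,
                           classifier = "nnls",
                           spec = kernel_spec("linear"), lambda_sparse = 0,
                           decision_rule = "min_class_residual",
                           seed = 1L) {
  X <- as.matrix(X)
  n <- ncol(X)
  if (folds < 2) stop("folds must be >= 2")
  if (n < folds) stop("need at least as many samples as folds")
  clf <- resolve_classifier(classifier, spec, lambda_sparse, decision_rule)
  acc <- matrix(NA_real_, runs, folds)
  for (r in seq_len(runs)) {
    fold_id <- with_seed(seed + r - 1L, stratified_folds(labels, folds))
    for (f in seq_len(folds)) {
      te <- fold_id == f
      pred <- clf(X[, !te, drop = FALSE], labels[!te], X[, te, drop = FALSE])
      acc[r, f] <- mean(pred == labels[te])
    }
  }
  structure(list(fold_accuracies = acc, mean_accuracy = mean(acc),
                 std_accuracy = stats::sd(as.vector(acc)),
                 config = list(folds = folds, runs = runs, seed = seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d x %d-fold cross-validation: accuracy %.4f +/- %.4f\n",
              x$config$runs, x$config$folds, x$mean_accuracy,
              x$std_accuracy))
  invisible(x)
}

#' Mask a fixed fraction of entries as missing
#'
#' Sets exactly `round(rate * m * n)` uniformly chosen entries to `NaN`.
#'
#' @param X matrix.
#' @param rate missing rate in `[0, 1)`.
#' @param seed integer seed.
#' @return The masked matrix.
#' @export
mask_missing <- function(X, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  X <- as.matrix(X)
  n_miss <- round(rate * length(X))
  idx <- with_seed(seed, sample.int(length(X), n_miss))
  X[idx] <- NaN
  X
}

#' Missing-value robustness experiment
#'
#' For each missing rate, masks entries uniformly at random and evaluates
#' the NNLS classifier by cross-validation under each strategy:
#' `"ignore"` (the common-support inner products of
#' [missing_aware_gram()], no imputation) and `"zero_impute"` (missing
#' cells replaced by 0 before classification).
#'
#' @param X complete data matrix (m x n).
#' @param labels class labels.
#' @param rates missing rates, each in `[0, 1)`.
#' @param strategies subset of `c("ignore", "zero_impute")`.
#' @param folds,runs cross-validation layout.
#' @param lambda_sparse NNLS l1 weight.
#' @param seed integer seed (drives masking and fold splits).
#' @return data.frame with one row per (rate, strategy):
#'   `rate`, `strategy`, `mean_accuracy`, `std_accuracy`.
#' @export
missingness_experiment <- function(X, labels, rates,
                                   strategies = c("ignore", "zero_impute"),
                                   folds = 4L, runs = 1L, lambda_sparse = 0,
                                   seed = 1L) {
  strategies <- match.arg(strategies, c("ignore", "zero_impute"),
                          several.ok = TRUE)
  out <- NULL
  for (rate in rates) {
    Xm <- if (rate > 0) mask_missing(X, rate, seed = seed + round(1e4 * rate))
          else as.matrix(X)
    for (strat in strategies) {
      Xs <- Xm
      if (strat == "zero_impute") Xs[is.na(Xs)] <- 0
      cv <- cross_validate(Xs, labels, folds = folds, runs = runs,
                           classifier = "nnls",
                           lambda_sparse = lambda_sparse, seed = seed)
      out <- rbind(out, data.frame(rate = rate, strategy = strat,
                                   mean_accuracy = cv$mean_accuracy,
                                   std_accuracy = cv$std_accuracy))
    }
  }
  out
}

#' Noise robustness experiment
#'
#' Adds Gaussian noise of increasing variance to a class-structured matrix
#' and tracks the accuracy of the NNLS classifier against the 1-NN baseline
#' on a held-out test half, averaged over seeds.
#'
#' @param X complete data matrix (m x n).
#' @param labels class labels.
#' @param variances Gaussian noise variances to sweep.
#' @param n_seeds number of noise/split replicates per variance.
#' @param classifiers subset of `c("nnls", "1nn")`.
#' @param lambda_sparse NNLS l1 weight.
#' @param seed base seed.
#' @return data.frame with `variance`, `classifier`, `mean_accuracy`,
#'   `std_accuracy` (across seeds).
#' @export
noise_experiment <- function(X, labels, variances = seq(0, 4, by = 0.5),
                             n_seeds = 20L, classifiers = c("nnls", "1nn"),
                             lambda_sparse = 0, seed = 1L) {
  X <- as.matrix(X)
  n <- ncol(X)
  out <- NULL
  for (v in variances) {
    accs <- matrix(NA_real_, n_seeds, length(classifiers),
                   dimnames = list(NULL, classifiers))
    for (s in seq_len(n_seeds)) {
      seed_s <- seed + 1000L * s + round(100 * v)
      Xn <- with_seed(seed_s,
                      X + matrix(stats::rnorm(length(X), sd = sqrt(v)),
                                 nrow(X)))
      split <- with_seed(seed_s + 1L, stratified_folds(labels, 2L))
      tr <- split == 1L
      for (cl in classifiers) {
        fn <- resolve_classifier(cl, kernel_spec("linear"), lambda_sparse,
                                 "min_class_residual")
        pred <- fn(Xn[, tr, drop = FALSE], labels[tr],
                   Xn[, !tr, drop = FALSE])
        accs[s, cl] <- mean(pred == labels[!tr])
      }
    }
    for (cl in classifiers)
      out <- rbind(out, data.frame(variance = v, classifier = cl,
                                   mean_accuracy = mean(accs[, cl]),
                                   std_accuracy = stats::sd(accs[, cl])))
  }
  out
}
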