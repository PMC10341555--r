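# From-scratch Relief-F feature weighting, plus impurity-based
# extremely-randomized-trees importance sharing the same ranking contract.

#' Assemble a feature matrix for ranking/classification
#'
#' @param X Numeric matrix, subjects in rows, features in columns (named).
#' @param y Binary class vector (0/1 or logical), one per row.
#' @param impute Impute missing entries with the column median (computed on
#'   `X` itself) before validation; all-missing columns become 0. Default
#'   TRUE. The cross-validation pipeline does its own fold-internal
#'   imputation and passes `impute = FALSE` matrices around.
#' @return A `tug_feature_matrix`: list with `X`, `y`, `feature_names`.
#' @export
feature_matrix <- function(X, y, impute = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.integer(y)
  if (length(y) != nrow(X)) stopf("y length (%d) != rows of X (%d)", length(y), nrow(X))
  if (!all(y %in% c(0L, 1L))) stopf("y must be binary 0/1")
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  if (impute) X <- impute_median(X)
  if (any(!is.finite(X))) stopf("X contains non-finite entries after imputation")
  structure(list(X = X, y = y, feature_names = colnames(X)),
            class = "tug_feature_matrix")
}

# median imputation per column; all-missing columns become 0
impute_median <- function(X, stats = NULL) {
  if (is.null(stats)) stats <- apply(X, 2L, function(col) {
    m <- median(col[is.finite(col)])
    if (is.na(m)) 0 else m
  })
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- stats[[j]]
  }
  attr(X, "impute_stats") <- stats
  X
}

#' Relief-F parameters
#' @param k Nearest neighbors per class (default 10; clipped to class size
#'   minus one with a warning when a class is small).
#' @param m_iters Number of iterations; `NULL` (default) means one per
#'   sample, drawn uniformly with replacement.
#' @param seed RNG seed for the sample draws.
#' @export
relieff_params <- function(k = 10L, m_iters = NULL, seed = 1L) {
  if (!is_count(k)) stopf("k must be a positive integer")
  if (!is.null(m_iters) && !is_count(m_iters)) stopf("m_iters must be a positive integer")
  structure(list(k = as.integer(k),
                 m_iters = if (is.null(m_iters)) NULL else as.integer(m_iters),
                 seed = as.integer(seed)),
            class = "tug_relieff_params")
}

#' Relief-F feature weights
#'
#' Instance-based feature quality estimation. All weights start at 0; at
#' each of `m` iterations a sample `x_r` is drawn uniformly with
#' replacement, its `k` nearest hits (same class) and `k` nearest misses
#' per other class are found by Manhattan distance over min-max-scaled
#' features, and each neighbor `x_q` updates every feature weight by the
#' normalized feature difference `delta_j = |x_rj - x_qj| / range(F_j)`:
#' subtracted for hits, added for misses with prior weighting
#' `p(class_q) / (1 - p(class_r))`, and in both cases divided by
#' `m * d_rq` (the update is distance-weighted; zero-distance neighbors are
#' skipped). Features with zero range contribute no updates and end with
#' weight exactly 0. Fully deterministic given the seed: neighbor ties
#' break toward the lower sample index, ranking ties toward the lower
#' feature index.
#'
#' @param data A [feature_matrix()].
#' @param params A [relieff_params()].
#' @return A `tug_ranked_features`: list with `weights` (named), `ranking`
#'   (feature indices, descending weight) and `selector = "relieff"`.
#' @export
relieff_weights <- function(data, params = relieff_params()) {
  stopifnot(inherits(data, "tug_feature_matrix"),
            inherits(params, "tug_relieff_params"))
  X <- data$X; y <- data$y
  n <- nrow(X); p <- ncol(X)
  m_iters <- if (is.null(params$m_iters)) n else params$m_iters

  rng <- apply(X, 2L, function(col) max(col) - min(col))
  lo <- apply(X, 2L, min)
  Xs <- sweep(X, 2L, lo)
  nz <- rng > 0
  Xs[, nz] <- sweep(Xs[, nz, drop = FALSE], 2L, rng[nz], "/")
  Xs[, !nz] <- 0  # zero-range features: delta identically 0

  classes <- sort(unique(y))
  prior <- vapply(classes, function(c) mean(y == c), numeric(1))
  names(prior) <- as.character(classes)
  min_class <- min(table(y))
  k <- params$k
  if (k >= min_class) {
    k <- max(1L, min_class - 1L)
    warnf("relieff: k clipped to %d (smallest class has %d samples)", k, min_class)
  }

  draws <- with_seed(params$seed, sample.int(n, m_iters, replace = TRUE))
  W <- relieff_core(Xs, as.integer(y), as.integer(draws), as.integer(k),
                    as.numeric(prior), as.integer(classes))
  ranked_features(setNames(W, colnames(X)), "relieff")
}

# shared construction of the ranking object; ties break toward the lower
# feature index
ranked_features <- function(weights, selector) {
  ranking <- order(-weights, seq_along(weights))
  structure(list(weights = weights, ranking = ranking, selector = selector),
            class = "tug_ranked_features")
}

#' @export
print.tug_ranked_features <- function(x, n = 10L, ...) {
  cat(sprintf("<tug_ranked_features> selector = %s; top %d:\n", x$selector,
              min(n, length(x$ranking))))
  top <- x$ranking[seq_len(min(n, length(x$ranking)))]
  for (i in top)
    cat(sprintf("  %-20s %+.5f\n", names(x$weights)[i], x$weights[i]))
  invisible(x)
}

#' Top-k feature names of a ranking
#' @param ranked A `tug_ranked_features`.
#' @param k Number of features, `1 <= k <= n_features`.
#' @return Character vector of length `k`.
#' @export
top_k <- function(ranked, k) {
  stopifnot(inherits(ranked, "tug_ranked_features"))
  p <- length(ranked$ranking)
  if (!is_count(k) || k > p) stopf("k must be in 1..%d", p)
  names(ranked$weights)[ranked$ranking[seq_len(k)]]
}

#' Extremely-randomized-trees feature importance
#'
#' Fits an extra-trees ensemble (whole-sample trees, random split
#' thresholds, `sqrt(p)` candidate features per node, Gini impurity) and
#' returns mean-decrease-impurity importances normalized to sum to 1.
#' Constant features can never split and get importance exactly 0.
#'
#' @param data A [feature_matrix()].
#' @param n_trees Ensemble size (default 100).
#' @param seed RNG seed (deterministic importances for a fixed seed).
#' @return A `tug_ranked_features` with `selector = "etc"`.
#' @export
etc_importance <- function(data, n_trees = 100L, seed = 1L) {
  stopifnot(inherits(data, "tug_feature_matrix"))
  if (!is_count(n_trees)) stopf("n_trees must be a positive integer")
  p <- ncol(data$X)
  fit <- forest_fit(data$X, data$y, matrix(numeric(0), 0L, p),
                    as.integer(n_trees), max(1L, floor(sqrt(p))),
                    FALSE, TRUE, 1L, as.numeric(seed))
  imp <- fit$importance
  if (sum(imp) > 0) imp <- imp / sum(imp)
  ranked_features(setNames(imp, colnames(data$X)), "etc")
}

#' Random-forest classifier (fit and predict probabilities)
#'
#' Bootstrap bagging of Gini CART trees with exhaustive split search over
#' `sqrt(p)` candidate features per node; class-1 probabilities are
#' averaged leaf frequencies. Used as the pipeline's classifier stage.
#'
#' @param data A [feature_matrix()] (training set).
#' @param newdata Numeric matrix with the same columns (test set).
#' @param n_trees Ensemble size (default 100).
#' @param seed RNG seed.
#' @return Numeric vector of class-1 probabilities for `newdata` rows.
#' @export
rf_predict_prob <- function(data, newdata, n_trees = 100L, seed = 1L) {
  stopifnot(inherits(data, "tug_feature_matrix"))
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(data$X)) stopf("newdata has mismatched columns")
  p <- ncol(data$X)
  fit <- forest_fit(data$X, data$y, newdata, as.integer(n_trees),
                    max(1L, floor(sqrt(p))), TRUE, FALSE, 1L, as.numeric(seed))
  fit$prob
}
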