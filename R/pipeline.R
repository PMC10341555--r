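# Clinical labeling, the resampled selection/classification grid, best-model
# selection by mean AUC, and the repeated-feature intersections.

#' Derive the three clinical fall-risk labels
#'
#' `label_tug = 1` iff the TUG took strictly more than 12.47 s;
#' `label_sfbbs = 1` iff the SFBBS score is strictly below 23;
#' `label_multi` is their union (fall risk if either criterion flags).
#'
#' @param tug_seconds Positive TUG durations (vectorized).
#' @param sfbbs_score Integer scores in `[0, 28]` (vectorized).
#' @return data.frame with columns `tug_seconds`, `sfbbs_score`,
#'   `label_tug`, `label_sfbbs`, `label_multi` (integer 0/1).
#' @export
make_labels <- function(tug_seconds, sfbbs_score) {
  if (any(!is.finite(tug_seconds)) || any(tug_seconds <= 0))
    stopf("tug_seconds must be positive and finite")
  if (any(!is.finite(sfbbs_score)) || any(sfbbs_score < 0) ||
      any(sfbbs_score > 28) || any(sfbbs_score != floor(sfbbs_score)))
    stopf("sfbbs_score must be an integer in [0, 28]")
  label_tug <- as.integer(tug_seconds > 12.47)
  label_sfbbs <- as.integer(sfbbs_score < 23)
  data.frame(tug_seconds = tug_seconds, sfbbs_score = as.integer(sfbbs_score),
             label_tug = label_tug, label_sfbbs = label_sfbbs,
             label_multi = as.integer(label_tug | label_sfbbs))
}

#' Cross-validation configuration
#'
#' The resampling scheme is stratified shuffle-splits: `n_splits` random
#' train/test partitions with `test_fraction` held out per class (at least
#' one test sample per class). Feature selection runs on the training part
#' of each split only; missing values are imputed with training-fold
#' medians inside each split.
#'
#' @param n_splits Number of random splits (>= 2; default 100).
#' @param test_fraction Held-out fraction in (0, 1) (default 0.2).
#' @param stratified Stratify splits by class (default TRUE).
#' @param k_grid Feature-subset sizes to evaluate (default 5..30 by 5).
#' @param rf_trees Trees in the random-forest classifier (default 100).
#' @param etc_trees Trees in the extra-trees selector (default 100).
#' @param relieff_k Relief-F neighbors per class (default 10).
#' @param consensus Fraction of splits in which a feature must enter the
#'   top-k to belong to a best model's feature set (default 0.5).
#' @param seed Master seed; the whole grid is deterministic given it.
#' @export
cv_config <- function(n_splits = 100L, test_fraction = 0.2, stratified = TRUE,
                      k_grid = c(5L, 10L, 15L, 20L, 25L, 30L),
                      rf_trees = 100L, etc_trees = 100L, relieff_k = 10L,
                      consensus = 0.5, seed = 1L) {
  if (!is_count(n_splits) || n_splits < 2) stopf("n_splits must be >= 2")
  if (!is_scalar_num(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stopf("test_fraction must be in (0, 1)")
  if (!length(k_grid) || any(!vapply(k_grid, is_count, logical(1))))
    stopf("k_grid must be positive integers")
  structure(list(n_splits = as.integer(n_splits), test_fraction = test_fraction,
                 stratified = isTRUE(stratified),
                 k_grid = as.integer(sort(unique(k_grid))),
                 rf_trees = as.integer(rf_trees), etc_trees = as.integer(etc_trees),
                 relieff_k = as.integer(relieff_k), consensus = consensus,
                 seed = as.integer(seed)),
            class = "tug_cv_config")
}

#' Area under the ROC curve from scores
#'
#' Rank-based (Mann-Whitney) AUC with the standard midrank handling of
#' tied scores.
#' @param scores Numeric classifier scores.
#' @param y Binary labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stopf("AUC needs both classes")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# precision/recall/F1 at the 0.5 probability threshold; precision defined
# as 0 when nothing is predicted positive
threshold_metrics <- function(prob, y) {
  pred <- as.integer(prob > 0.5)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

# one stratified shuffle split; returns list(train, test) of row indices
stratified_split <- function(y, test_fraction, stratified) {
  n <- length(y)
  if (stratified) {
    test <- unlist(lapply(unique(y), function(cl) {
      rows <- which(y == cl)
      n_test <- max(1L, round(length(rows) * test_fraction))
      n_test <- min(n_test, length(rows) - 1L)  # keep the class in training
      sample(rows, n_test)
    }))
  } else {
    repeat {
      test <- sample.int(n, max(1L, round(n * test_fraction)))
      if (length(unique(y[test])) == 2L && length(unique(y[-test])) == 2L) break
    }
  }
  list(train = setdiff(seq_len(n), test), test = sort(test))
}

#' Run the selection/classification grid
#'
#' For each of `n_splits` stratified shuffle-splits: impute missing
#' features with training-fold medians, rank features on the training fold
#' with both selectors (Relief-F and extra-trees importance), then for each
#' `k` in `k_grid` train a random forest on the top-k training features and
#' score AUC (plus precision/recall/F1 at threshold 0.5) on the held-out
#' fold. Aggregates means and SDs over splits and records every split's
#' ranking so best-model feature sets can be formed by consensus.
#' Deterministic given `cfg$seed`.
#'
#' @param X Numeric matrix (subjects x features); may contain `NA`s.
#' @param y Binary label vector.
#' @param cfg A [cv_config()].
#' @return A `tug_eval_grid`: list with `cells` (data.frame of per-cell
#'   aggregate metrics), `rankings` (per selector, an `n_splits x p` matrix
#'   of feature indices in descending weight order), `cfg`,
#'   `feature_names`.
#' @export
run_grid <- function(X, y, cfg = cv_config()) {
  stopifnot(inherits(cfg, "tug_cv_config"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  p <- ncol(X)
  if (any(cfg$k_grid > p)) stopf("k_grid contains k > n_features (%d)", p)
  selectors <- c("relieff", "etc")

  seeds <- derive_seeds(cfg$seed, cfg$n_splits)
  rankings <- lapply(selectors, function(s)
    matrix(NA_integer_, cfg$n_splits, p))
  names(rankings) <- selectors
  metrics <- array(NA_real_,
                   dim = c(cfg$n_splits, length(selectors), length(cfg$k_grid), 4L),
                   dimnames = list(NULL, selectors, cfg$k_grid,
                                   c("auc", "precision", "recall", "f1")))

  for (s in seq_len(cfg$n_splits)) {
    sp_seeds <- derive_seeds(seeds[s], 4L)
    sp <- with_seed(sp_seeds[1L],
                    stratified_split(y, cfg$test_fraction, cfg$stratified))
    Xtr <- impute_median(X[sp$train, , drop = FALSE])
    Xte <- impute_median(X[sp$test, , drop = FALSE],
                         stats = attr(Xtr, "impute_stats"))
    ytr <- y[sp$train]; yte <- y[sp$test]

    fm <- feature_matrix(Xtr, ytr, impute = FALSE)
    ranked <- list(
      relieff = relieff_weights(fm, relieff_params(k = cfg$relieff_k,
                                                   seed = sp_seeds[2L])),
      etc = etc_importance(fm, n_trees = cfg$etc_trees, seed = sp_seeds[3L])
    )
    for (sel in selectors) {
      rankings[[sel]][s, ] <- ranked[[sel]]$ranking
      for (ki in seq_along(cfg$k_grid)) {
        feats <- top_k(ranked[[sel]], cfg$k_grid[ki])
        sub <- feature_matrix(Xtr[, feats, drop = FALSE], ytr, impute = FALSE)
        prob <- rf_predict_prob(sub, Xte[, feats, drop = FALSE],
                                n_trees = cfg$rf_trees, seed = sp_seeds[4L])
        metrics[s, sel, ki, ] <- c(auc_score(prob, yte),
                                   threshold_metrics(prob, yte))
      }
    }
  }

  cells <- do.call(rbind, lapply(selectors, function(sel) {
    do.call(rbind, lapply(seq_along(cfg$k_grid), function(ki) {
      m <- metrics[, sel, ki, , drop = FALSE]
      data.frame(selector = sel, k = cfg$k_grid[ki],
                 mean_auc = mean(m[, , , "auc"]), sd_auc = sd(m[, , , "auc"]),
                 mean_precision = mean(m[, , , "precision"]),
                 mean_recall = mean(m[, , , "recall"]),
                 mean_f1 = mean(m[, , , "f1"]))
    }))
  }))
  rownames(cells) <- NULL
  structure(list(cells = cells, rankings = rankings, cfg = cfg,
                 feature_names = colnames(X)),
            class = "tug_eval_grid")
}

#' Best grid cell per selector
#'
#' The `k` maximizing mean AUC for each selector; ties go to the smaller
#' `k` (the simpler model).
#' @param grid A `tug_eval_grid`.
#' @return data.frame with one row per selector: `selector`, `k`,
#'   `mean_auc`, `sd_auc`, `mean_precision`, `mean_recall`, `mean_f1`.
#' @export
select_best <- function(grid) {
  stopifnot(inherits(grid, "tug_eval_grid"))
  cells <- grid$cells
  if (any(!is.finite(cells$mean_auc))) stopf("grid contains failed cells")
  out <- do.call(rbind, lapply(split(cells, cells$selector), function(df) {
    df <- df[order(df$k), ]
    df[which.max(df$mean_auc), ]  # which.max takes the first (smallest k) tie
  }))
  rownames(out) <- NULL
  out
}

# consensus feature set of one (selector, k) cell: features in the top-k in
# at least `consensus` of the splits, ordered by frequency then catalogue
# position
consensus_set <- function(grid, selector, k, consensus) {
  R <- grid$rankings[[selector]]
  topk <- R[, seq_len(k), drop = FALSE]
  freq <- tabulate(as.integer(topk), nbins = length(grid$feature_names)) / nrow(R)
  idx <- which(freq >= consensus)
  idx <- idx[order(-freq[idx], idx)]
  grid$feature_names[idx]
}

#' Intersect the feature sets of the best models
#'
#' For every clinical labeling, forms each selector's best-model feature
#' set (consensus membership across splits at the best `k`), intersects
#' the Relief-F and extra-trees sets, and stars the features present in
#' every labeling's intersection.
#'
#' @param grids Named list of `tug_eval_grid`s, one per labeling (e.g.
#'   `sfbbs`, `tug`, `multi`), all over the same feature set.
#' @param consensus Consensus threshold; defaults to the first grid's
#'   `cfg$consensus`.
#' @return A `tug_important_report`: `per_label` (for each labeling: the
#'   best `k` and set per selector plus their intersection) and `starred`
#'   (the intersection across all labelings).
#' @export
intersect_important <- function(grids, consensus = NULL) {
  stopifnot(is.list(grids), length(grids) >= 1L, !is.null(names(grids)))
  if (is.null(consensus)) consensus <- grids[[1L]]$cfg$consensus
  per_label <- lapply(grids, function(grid) {
    best <- select_best(grid)
    sets <- lapply(seq_len(nrow(best)), function(i)
      consensus_set(grid, best$selector[i], best$k[i], consensus))
    names(sets) <- best$selector
    inter <- intersect(sets$relieff, sets$etc)
    if (length(inter) == 0L)
      warnf("empty best-model intersection for one labeling")
    list(best = best, relieff_set = sets$relieff, etc_set = sets$etc,
         intersection = inter)
  })
  starred <- Reduce(intersect, lapply(per_label, `[[`, "intersection"))
  structure(list(per_label = per_label, starred = starred),
            class = "tug_important_report")
}

#' @export
print.tug_important_report <- function(x, ...) {
  cat("<tug_important_report>\n")
  for (lab in names(x$per_label)) {
    pl <- x$per_label[[lab]]
    cat(sprintf("  %s: |relieff| = %d, |etc| = %d, intersection = {%s}\n",
                lab, length(pl$relieff_set), length(pl$etc_set),
                paste(pl$intersection, collapse = ", ")))
  }
  cat(sprintf("  starred (all labelings): {%s}\n",
              paste(x$starred, collapse = ", ")))
  invisible(x)
}

#' Cross-cohort intersection of important features
#'
#' Per labeling, intersects two cohorts' best-model intersections, and
#' flags the features starred in both cohorts.
#' @param report_a,report_b `tug_important_report`s over the same labelings.
#' @return List with `per_label` (named character vectors) and `starred`.
#' @export
compare_reports <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "tug_important_report"),
            inherits(report_b, "tug_important_report"))
  labs <- intersect(names(report_a$per_label), names(report_b$per_label))
  per_label <- lapply(labs, function(lab)
    intersect(report_a$per_label[[lab]]$intersection,
              report_b$per_label[[lab]]$intersection))
  names(per_label) <- labs
  list(per_label = per_label,
       starred = intersect(report_a$starred, report_b$starred))
}

#' Write the evaluation report to disk
#'
#' Writes the AUC summary over all grid cells, the best-model statistics,
#' the per-labeling important-feature sets (starred features marked `*`)
#' and a human-readable Markdown digest.
#'
#' @param report A `tug_important_report`.
#' @param grids The named grid list that produced it.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(report, grids, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stopf("cannot create directory %s", directory)
  auc_f <- file.path(directory, "auc_summary.csv")
  auc <- do.call(rbind, lapply(names(grids), function(lab)
    cbind(label = lab, grids[[lab]]$cells)))
  write.csv(auc, auc_f, row.names = FALSE, quote = FALSE)

  best_f <- file.path(directory, "best_models.csv")
  best <- do.call(rbind, lapply(names(report$per_label), function(lab)
    cbind(label = lab, report$per_label[[lab]]$best)))
  write.csv(best, best_f, row.names = FALSE, quote = FALSE)

  imp_f <- file.path(directory, "important_features.csv")
  imp <- do.call(rbind, lapply(names(report$per_label), function(lab) {
    inter <- report$per_label[[lab]]$intersection
    if (length(inter) == 0L) return(NULL)
    data.frame(label = lab, feature = inter,
               starred = ifelse(inter %in% report$starred, "*", ""))
  }))
  if (is.null(imp))
    imp <- data.frame(label = character(0), feature = character(0),
                      starred = character(0))
  write.csv(imp, imp_f, row.names = FALSE, quote = FALSE)

  md_f <- file.path(directory, "report.md")
  lines <- c("# Fall-risk feature report", "",
             "## Best models (mean AUC over splits)", "")
  for (lab in names(report$per_label)) {
    b <- report$per_label[[lab]]$best
    lines <- c(lines, sprintf("- %s: %s", lab,
                              paste(sprintf("%s k=%d AUC=%.3f", b$selector, b$k,
                                            b$mean_auc), collapse = "; ")))
  }
  lines <- c(lines, "", "## Important features (best-model intersections)", "")
  for (lab in names(report$per_label)) {
    inter <- report$per_label[[lab]]$intersection
    lines <- c(lines, sprintf("- %s: %s", lab,
                              if (length(inter)) paste(inter, collapse = ", ")
                              else "(empty)"))
  }
  lines <- c(lines, "",
             sprintf("Starred across all labelings: %s",
                     if (length(report$starred)) paste(report$starred, collapse = ", ")
                     else "(none)"))
  writeLines(lines, md_f)
  invisible(c(auc_f, best_f, imp_f, md_f))
}
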