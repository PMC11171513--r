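#' Classification metric bundle
#'
#' Computes the full evaluation suite for hard 0/1 predictions with an
#' optional class-1 score: accuracy, precision/recall/F1 for class 1, AUC
#' (rank statistic, ties counted half), RMSE on the 0/1 labels, Pearson
#' correlation R between truth and prediction, and the sample standard
#' deviation of the signed residuals. For hard labels the identity
#' `rmse^2 = 1 - accuracy` holds exactly.
#'
#' @param y true 0/1 labels.
#' @param yhat predicted 0/1 labels.
#' @param scores optional numeric class-1 scores; if absent, AUC is `NA`.
#' @return object of class `eval_report` (a list of metrics plus the 2x2
#'   `confusion` matrix).
#' @export
compute_metrics <- function(y, yhat, scores = NULL) {
  stopifnot(length(y) == length(yhat))
  y <- as.integer(y)
  yhat <- as.integer(yhat)
  tp <- sum(y == 1 & yhat == 1)
  tn <- sum(y == 0 & yhat == 0)
  fp <- sum(y == 0 & yhat == 1)
  fn <- sum(y == 1 & yhat == 0)
  n <- length(y)
  accuracy <- (tp + tn) / n
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  auc <- if (is.null(scores)) {
    NA_real_
  } else {
    n1 <- sum(y == 1)
    n0 <- n - n1
    if (n1 == 0 || n0 == 0) {
      NA_real_
    } else {
      r <- rank(scores)
      (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  resid <- y - yhat
  rmse <- sqrt(mean(resid^2))
  r_cor <- if (stats::sd(yhat) == 0 || stats::sd(y) == 0) {
    NA_real_
  } else {
    stats::cor(y, yhat)
  }
  structure(
    list(accuracy = accuracy, precision = precision, recall = recall,
         f1 = f1, auc = auc, rmse = rmse, r = r_cor,
         std = stats::sd(resid),
         confusion = matrix(c(tn, fn, fp, tp), 2, 2,
                            dimnames = list(pred = c("0", "1"),
                                            true = c("0", "1")))),
    class = "eval_report"
  )
}

#' @method print eval_report
#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> acc %.4f  prec %.4f  rec %.4f  F1 %.4f  AUC %.4f\n",
    x$accuracy, x$precision, x$recall, x$f1, x$auc))
  cat(sprintf("              rmse %.4f  R %.4f  std %.4f\n", x$rmse, x$r, x$std))
  invisible(x)
}

# Pooled out-of-fold predictions for one subset/model/fold partition.
# Numeric features are standardized inside each fold with the training
# fold's mean and population SD (no leakage into the held-out fold).
cv_predict <- function(table, subset, config, fold_ids, seed = 1L) {
  idx <- match(subset, table$meta$name)
  if (anyNA(idx)) stop("unknown feature(s): ",
                       paste(setdiff(subset, table$meta$name), collapse = ", "))
  X <- table$values[, idx, drop = FALSE]
  if (anyNA(X)) stop("cross-validation requires a complete table (impute first)")
  y <- table$labels
  is_num <- table$meta$kind[idx] == "numeric"
  pred <- integer(length(y))
  score <- numeric(length(y))
  for (f in sort(unique(fold_ids))) {
    te <- fold_ids == f
    Xtr <- X[!te, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    if (length(unique(y[!te])) < 2) {
      stop("degenerate single-class training fold")
    }
    for (j in which(is_num)) {
      m <- mean(Xtr[, j])
      s <- pop_sd(Xtr[, j])
      if (s > 0) {
        Xtr[, j] <- (Xtr[, j] - m) / s
        Xte[, j] <- (Xte[, j] - m) / s
      }
    }
    out <- fit_predict(config, Xtr, y[!te], Xte, seed = seed + f)
    pred[te] <- out$pred
    score[te] <- out$score
  }
  list(y = y, pred = pred, score = score)
}

# Mean CV accuracy of a feature subset; the empty subset scores the
# majority-class rate (the no-information baseline the wrapper search
# starts from when the seed subset is empty).
cv_accuracy <- function(table, subset, config, fold_ids, seed = 1L) {
  if (!length(subset)) {
    return(max(table(table$labels)) / length(table$labels))
  }
  out <- cv_predict(table, subset, config, fold_ids, seed)
  mean(out$pred == out$y)
}

#' Stratified k-fold cross-validation of one subset/model pair
#'
#' Fits the configured classifier on each training fold (with fold-internal
#' standardization of numeric features) and pools the held-out predictions
#' into a single [compute_metrics()] report.
#'
#' @param table a complete [feature_table()].
#' @param subset character vector of feature names to use.
#' @param config a [model_config()].
#' @param folds number of folds (default 5).
#' @param seed integer seed fixing the fold partition and any stochastic
#'   fitter.
#' @return an `eval_report`.
#' @export
cross_validate <- function(table, subset, config, folds = 5L, seed = 1L) {
  stopifnot(length(subset) >= 1)
  fold_ids <- stratified_folds(table$labels, folds, seed)
  out <- cv_predict(table, subset, config, fold_ids, seed)
  rep <- compute_metrics(out$y, out$pred, out$score)
  rep$fold_ids <- fold_ids
  rep
}

#' Exhaustive grid search by cross-validated accuracy
#'
#' Evaluates every parameter combination of `grid` by mean CV accuracy
#' under a fixed fold partition and returns the winning [model_config()].
#' Ties go to the first combination in grid order, so pass the grid in
#' lexicographic order if that tie-break is wanted.
#'
#' @param table a complete [feature_table()].
#' @param subset feature names to train on.
#' @param model model name (see [model_config()]).
#' @param grid data frame (or list of named lists) of parameter
#'   combinations; one row/element per candidate.
#' @param folds,seed cross-validation settings.
#' @return the winning `model_config`, with the per-candidate accuracy
#'   table attached as attribute `"results"`.
#' @export
grid_search <- function(table, subset, model, grid, folds = 5L, seed = 1L) {
  if (is.data.frame(grid)) {
    grid <- lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
  }
  if (!length(grid)) stop("grid must be non-empty")
  fold_ids <- stratified_folds(table$labels, folds, seed)
  accs <- vapply(grid, function(par) {
    cv_accuracy(table, subset, model_config(model, params = par),
                fold_ids, seed)
  }, numeric(1))
  best <- which.max(accs) # which.max takes the first maximum: grid-order tie-break
  winner <- model_config(model, params = grid[[best]])
  attr(winner, "results") <- data.frame(
    candidate = seq_along(grid), accuracy = accs
  )
  attr(winner, "accuracy") <- accs[best]
  winner
}

#' Benchmark HC-MFS against the filter baselines
#'
#' Runs HC-MFS and the four filter methods (Fisher score, Relief-F, mutual
#' information, distance correlation) on the same table, evaluating every
#' method's subset with the same classifier and the same fold partition
#' (paired comparison). Filter baselines contribute their top-`k` ranking;
#' HC-MFS contributes the subset found by [hc_mfs_select()].
#'
#' @param table a complete [feature_table()].
#' @param methods methods to run, a subset of
#'   `c("HCMFS", "FS", "R_F", "MI", "DCFS")`.
#' @param model a [model_config()] shared by all methods.
#' @param k subset size for the filter baselines (default 12).
#' @param folds,seed cross-validation settings.
#' @param config optional [hcmfs_config()] for the HC-MFS run; defaults to
#'   one built from `model`, `folds` and `seed`.
#' @return named list of `eval_report`s, one per method, each carrying the
#'   chosen `subset` as an extra element.
#' @export
compare_methods <- function(table,
                            methods = c("HCMFS", "FS", "R_F", "MI", "DCFS"),
                            model = model_config("RF"), k = 12L,
                            folds = 5L, seed = 1L, config = NULL) {
  known <- c("HCMFS", "FS", "R_F", "MI", "DCFS")
  if (!all(methods %in% known)) {
    stop("unknown method(s): ", paste(setdiff(methods, known), collapse = ", "))
  }
  stopifnot(k <= ncol(table$values))
  reports <- list()
  for (m in methods) {
    subset <- if (m == "HCMFS") {
      cfg <- config %||% hcmfs_config(classifier = model, cv_folds = folds,
                                      seed = seed)
      hc_mfs_select(table, cfg)$subset
    } else {
      top_k(rank_features(table, method = m, seed = seed), k)
    }
    rep <- cross_validate(table, subset, model, folds = folds, seed = seed)
    rep$subset <- subset
    reports[[m]] <- rep
  }
  reports
}

#' Reference parameter settings for the five classifiers
#'
#' Reads the bundled JSON of per-method, per-model parameter settings and
#' preferred preprocessing variants used by the benchmark study this
#' package reimplements.
#'
#' @return nested list: method -> model -> list(params, dataset).
#' @export
model_grids <- function() {
  path <- system.file("extdata", "model_grids.json", package = "hcmfs",
                      mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = FALSE)
}
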