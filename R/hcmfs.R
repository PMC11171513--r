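#' HC-MFS configuration
#'
#' Settings for the dual feature-selection pipeline: Ward clustering of
#' features into `k_classes`, mean-Fisher-score seeding, and greedy
#' forward/backward wrapper searches scored by `cv_folds`-fold
#' cross-validated accuracy of `classifier`.
#'
#' @param k_classes number of feature clusters (default 3).
#' @param classifier a [model_config()] driving the wrapper searches
#'   (default unpenalized logistic regression, cheap and deterministic).
#' @param cv_folds cross-validation folds (default 5).
#' @param seed integer seed fixing the fold partition for the whole run.
#' @param candidate_order visiting order of wrapper candidates; currently
#'   `"fisher_desc"` (descending Fisher score forward, ascending backward).
#' @return object of class `hcmfs_config`.
#' @export
hcmfs_config <- function(k_classes = 3L, classifier = model_config("LR"),
                         cv_folds = 5L, seed = 1L,
                         candidate_order = "fisher_desc") {
  stopifnot(k_classes >= 1, cv_folds >= 2)
  candidate_order <- match.arg(candidate_order, "fisher_desc")
  structure(
    list(k_classes = as.integer(k_classes), classifier = classifier,
         cv_folds = as.integer(cv_folds), seed = as.integer(seed),
         candidate_order = candidate_order),
    class = "hcmfs_config"
  )
}

#' Mean Fisher score per feature class
#'
#' @param scores a `score_vector` of Fisher scores covering every assigned
#'   feature.
#' @param classes a `feature_classes` assignment from [cut_tree()].
#' @return named numeric vector: class id -> arithmetic mean Fisher score.
#' @export
mean_fisher_by_class <- function(scores, classes) {
  stopifnot(inherits(scores, "score_vector"),
            inherits(classes, "feature_classes"))
  missing <- setdiff(names(classes$classes), names(scores$scores))
  if (length(missing)) {
    stop("no score for feature(s): ", paste(missing, collapse = ", "))
  }
  out <- vapply(seq_len(classes$k), function(c_id) {
    mean(scores$scores[names(classes$classes)[classes$classes == c_id]])
  }, numeric(1))
  names(out) <- as.character(seq_len(classes$k))
  out
}

#' Seed subset by per-class mean-Fisher-score thresholding
#'
#' Selects the features whose Fisher score *strictly* exceeds the mean
#' Fisher score of their own cluster — the features with superior class
#' differentiation ability relative to their redundancy group. A cluster
#' whose scores are all equal contributes nothing (strict inequality).
#'
#' @inheritParams mean_fisher_by_class
#' @return object of class `initial_subset`: list with `features` (in
#'   descending Fisher-score order), `class_means` and `fisher_scores`.
#' @export
initial_subset <- function(scores, classes) {
  mfs <- mean_fisher_by_class(scores, classes)
  keep <- names(classes$classes)[
    scores$scores[names(classes$classes)] >
      mfs[as.character(classes$classes)]
  ]
  ord <- order(-scores$scores[keep])
  structure(
    list(features = keep[ord], class_means = mfs, fisher_scores = scores),
    class = "initial_subset"
  )
}

#' @method print initial_subset
#' @export
print.initial_subset <- function(x, ...) {
  cat(sprintf("<initial_subset> %d features above their class mean\n",
              length(x$features)))
  cat("  class means:",
      paste(sprintf("%s=%.4g", names(x$class_means), x$class_means),
            collapse = ", "), "\n")
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

selection_result <- function(subset, direction, trace, extras = list()) {
  res <- c(
    list(subset = subset, direction = direction,
         accuracy_trace = trace,
         final_accuracy = max(vapply(trace, `[[`, numeric(1), "accuracy"))),
    extras
  )
  class(res) <- "selection_result"
  res
}

#' @method print selection_result
#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s search: %d features, CV accuracy %.4f\n",
              x$direction, length(x$subset), x$final_accuracy))
  cat("  subset:", paste(x$subset, collapse = ", "), "\n")
  invisible(x)
}

# Fisher-score visiting order of a candidate pool (ties by column order).
candidate_order <- function(table, pool, decreasing) {
  fs <- vapply(pool, function(f) {
    fisher_score(table$values[, f], table$labels)
  }, numeric(1))
  pool[order(if (decreasing) -fs else fs, match(pool, table$meta$name))]
}

#' Greedy forward wrapper search
#'
#' Starting from the seed subset, visits every remaining feature exactly
#' once in descending Fisher-score order and adds it permanently iff it
#' *strictly* increases the cross-validated accuracy of the configured
#' classifier. The fold partition is frozen once for the whole search, so
#' all accuracy comparisons are paired.
#'
#' @param table a complete [feature_table()].
#' @param seed_subset character vector of protected starting features
#'   (possibly empty; the empty subset scores the majority-class rate).
#' @param config an [hcmfs_config()].
#' @return a `selection_result` with `direction = "forward"` and an
#'   `accuracy_trace` of `(size, accuracy)` records for the seed state and
#'   every accepted addition.
#' @export
forward_search <- function(table, seed_subset, config = hcmfs_config()) {
  stopifnot(inherits(table, "feature_table"))
  if (!ncol(table$values)) stop("table has no features")
  stopifnot(all(seed_subset %in% feature_names(table)))
  fold_ids <- stratified_folds(table$labels, config$cv_folds, config$seed)
  current <- seed_subset
  acc <- cv_accuracy(table, current, config$classifier, fold_ids, config$seed)
  trace <- list(list(size = length(current), accuracy = acc))
  pool <- candidate_order(table, setdiff(feature_names(table), current),
                          decreasing = TRUE)
  for (cand in pool) {
    acc_new <- cv_accuracy(table, c(current, cand), config$classifier,
                           fold_ids, config$seed)
    if (acc_new > acc) {
      current <- c(current, cand)
      acc <- acc_new
      trace <- c(trace, list(list(size = length(current), accuracy = acc)))
    }
  }
  selection_result(current, "forward", trace,
                   extras = list(seed_subset = seed_subset))
}

#' Greedy backward wrapper search
#'
#' Starting from the *full* feature set, visits every non-seed feature
#' exactly once in ascending Fisher-score order and removes it permanently
#' iff the removal does not decrease cross-validated accuracy. Seed
#' features are protected and never removed, so the result always contains
#' the seed subset.
#'
#' @inheritParams forward_search
#' @return a `selection_result` with `direction = "backward"`.
#' @export
backward_search <- function(table, seed_subset, config = hcmfs_config()) {
  stopifnot(inherits(table, "feature_table"))
  if (!ncol(table$values)) stop("table has no features")
  stopifnot(all(seed_subset %in% feature_names(table)))
  fold_ids <- stratified_folds(table$labels, config$cv_folds, config$seed)
  current <- feature_names(table)
  acc <- cv_accuracy(table, current, config$classifier, fold_ids, config$seed)
  trace <- list(list(size = length(current), accuracy = acc))
  pool <- candidate_order(table, setdiff(current, seed_subset),
                          decreasing = FALSE)
  for (cand in pool) {
    acc_new <- cv_accuracy(table, setdiff(current, cand), config$classifier,
                           fold_ids, config$seed)
    if (acc_new >= acc) {
      current <- setdiff(current, cand)
      acc <- acc_new
      trace <- c(trace, list(list(size = length(current), accuracy = acc)))
    }
  }
  selection_result(current, "backward", trace,
                   extras = list(seed_subset = seed_subset))
}

#' HC-MFS dual feature selection
#'
#' The full five-step pipeline:
#' \enumerate{
#'   \item Ward-cluster the features (on z-scored columns) into
#'     `k_classes` redundancy groups.
#'   \item Compute each feature's Fisher score and each cluster's mean
#'     Fisher score (MFS).
#'   \item Seed the subset with the features whose score strictly exceeds
#'     their cluster's MFS.
#'   \item Refine by a greedy forward search (from the seed) and a greedy
#'     backward search (from the full set, seed protected), each visiting
#'     every candidate once under cross-validated classifier accuracy.
#'   \item Return the direction with the higher final accuracy; on an
#'     exact tie the smaller subset, and on a tie in both, forward.
#' }
#'
#' @param table a complete, preprocessed [feature_table()].
#' @param config an [hcmfs_config()].
#' @return the winning `selection_result`, with the clustering
#'   (`feature_classes`), seed (`initial_subset`) and both search results
#'   attached as elements `classes`, `seed`, `forward`, `backward`.
#' @export
hc_mfs_select <- function(table, config = hcmfs_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "hcmfs_config"))
  std <- standardize_table(table)
  dendro <- ward_cluster(feature_distance_matrix(std))
  classes <- cut_tree(dendro, min(config$k_classes, ncol(table$values)))
  fs <- rank_features(table, "FS")
  seed_sub <- initial_subset(fs, classes)
  fwd <- forward_search(table, seed_sub$features, config)
  bwd <- backward_search(table, seed_sub$features, config)
  winner <- if (bwd$final_accuracy > fwd$final_accuracy) {
    bwd
  } else if (fwd$final_accuracy > bwd$final_accuracy) {
    fwd
  } else if (length(bwd$subset) < length(fwd$subset)) {
    bwd
  } else {
    fwd
  }
  winner$classes <- classes
  winner$dendrogram <- dendro
  winner$seed <- seed_sub
  winner$forward <- fwd
  winner$backward <- bwd
  winner
}
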