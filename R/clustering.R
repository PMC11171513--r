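#' Euclidean distance between standardized feature columns
#'
#' Views each feature as a vector over samples, z-scores it (population
#' SD), and returns the symmetric Euclidean distance matrix between
#' features. Two perfectly correlated features are at distance 0. If the
#' numeric columns are not already standardized a warning is emitted and
#' the standardization is applied internally.
#'
#' @param table a complete [feature_table()].
#' @return symmetric `p x p` distance matrix with feature dimnames.
#' @export
feature_distance_matrix <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (anyNA(table$values)) stop("distance matrix requires a complete table")
  num <- which(table$meta$kind == "numeric")
  needs <- FALSE
  for (j in num) {
    x <- table$values[, j]
    if (abs(mean(x)) > 1e-6 || abs(pop_sd(x) - 1) > 1e-6) {
      if (pop_sd(x) > 0) needs <- TRUE
    }
  }
  if (needs) {
    warning("numeric features are not standardized; standardizing internally")
  }
  # z-score every column (including categorical codes) so the Euclidean
  # geometry is scale-free: d^2(f, g) = 2 n (1 - cor(f, g))
  Z <- apply(table$values, 2, function(x) {
    s <- pop_sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  d <- as.matrix(stats::dist(t(Z)))
  dimnames(d) <- list(table$meta$name, table$meta$name)
  d
}

#' Ward agglomerative clustering of features
#'
#' Agglomerates the items of a distance matrix by Ward's minimum-variance
#' criterion (Lance–Williams update on squared distances, merge heights on
#' the distance scale), via [stats::hclust()] with `method = "ward.D2"`.
#' Deterministic for a given distance matrix; heights are non-decreasing.
#'
#' @param dist_matrix symmetric distance matrix (e.g. from
#'   [feature_distance_matrix()]), `n >= 2`.
#' @return an object of class `dendrogram_ward`: list with `merges`
#'   (data frame `node_a`, `node_b`, `height`, `new_size`; negative ids
#'   are leaves), `leaf_names`, and the underlying `hclust` object.
#' @export
ward_cluster <- function(dist_matrix) {
  dist_matrix <- as.matrix(dist_matrix)
  if (nrow(dist_matrix) != ncol(dist_matrix)) {
    stop("distance matrix must be square")
  }
  if (nrow(dist_matrix) < 2) stop("need at least 2 items to cluster")
  if (max(abs(dist_matrix - t(dist_matrix))) > 1e-8) {
    stop("distance matrix must be symmetric")
  }
  hc <- stats::hclust(stats::as.dist(dist_matrix), method = "ward.D2")
  sizes <- integer(nrow(hc$merge))
  size_of <- function(id, step) if (id < 0) 1L else sizes[id]
  for (s in seq_len(nrow(hc$merge))) {
    sizes[s] <- size_of(hc$merge[s, 1]) + size_of(hc$merge[s, 2])
  }
  merges <- data.frame(
    node_a = hc$merge[, 1], node_b = hc$merge[, 2],
    height = hc$height, new_size = sizes
  )
  structure(
    list(merges = merges,
         leaf_names = hc$labels %||% as.character(seq_len(nrow(dist_matrix))),
         hclust = hc),
    class = "dendrogram_ward"
  )
}

#' @method print dendrogram_ward
#' @export
print.dendrogram_ward <- function(x, ...) {
  cat(sprintf("<dendrogram_ward> %d leaves, %d merges, top height %.4g\n",
              length(x$leaf_names), nrow(x$merges), max(x$merges$height)))
  invisible(x)
}

#' Cut a feature dendrogram into k classes
#'
#' Returns the partition present after `n - k` merges, i.e. the k clusters
#' obtained by removing the `k - 1` highest merges. Class ids are numbered
#' 1..k by first-appearing leaf.
#'
#' @param dendro a `dendrogram_ward` from [ward_cluster()].
#' @param k number of classes, `1 <= k <= n`.
#' @return object of class `feature_classes`: list with `classes` (named
#'   integer vector, feature -> class id) and `k`.
#' @export
cut_tree <- function(dendro, k) {
  stopifnot(inherits(dendro, "dendrogram_ward"))
  n <- length(dendro$leaf_names)
  if (k < 1 || k > n) stop("k must lie in 1..", n)
  cl <- stats::cutree(dendro$hclust, k = k)
  names(cl) <- dendro$leaf_names
  structure(list(classes = cl, k = as.integer(k)), class = "feature_classes")
}

#' @method print feature_classes
#' @export
print.feature_classes <- function(x, ...) {
  cat(sprintf("<feature_classes> k = %d\n", x$k))
  for (c_id in seq_len(x$k)) {
    cat(sprintf("  %d: %s\n", c_id,
                paste(names(x$classes)[x$classes == c_id], collapse = ", ")))
  }
  invisible(x)
}

#' Suggest a class count by mean silhouette width
#'
#' Exploratory helper: evaluates candidate `k` values by the mean
#' silhouette width of the feature partition under the supplied distance
#' matrix and returns the best. Never used to override an explicit `k`.
#'
#' @param dendro a `dendrogram_ward`.
#' @param dist_matrix the distance matrix the dendrogram was built from.
#' @param k_range candidate class counts.
#' @return the candidate `k` with the highest mean silhouette width.
#' @export
suggest_k <- function(dendro, dist_matrix, k_range = 2:6) {
  dist_matrix <- as.matrix(dist_matrix)
  n <- length(dendro$leaf_names)
  k_range <- k_range[k_range >= 2 & k_range < n]
  mean_sil <- vapply(k_range, function(k) {
    cl <- cut_tree(dendro, k)$classes
    s <- vapply(seq_len(n), function(i) {
      own <- which(cl == cl[i])
      own <- own[own != i]
      if (!length(own)) return(0)
      a <- mean(dist_matrix[i, own])
      b <- min(vapply(setdiff(unique(cl), cl[i]), function(o) {
        mean(dist_matrix[i, cl == o])
      }, numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1))
    mean(s)
  }, numeric(1))
  k_range[which.max(mean_sil)]
}
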