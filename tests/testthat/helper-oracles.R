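# Independent oracles: brute-force re-implementations used only to verify
# the package's fast paths. They deliberately share no code with R/.

# Naive Ward agglomeration over the rows of X: at every step recompute the
# Ward merge cost sqrt(2|A||B|/(|A|+|B|)) * ||mean_A - mean_B|| for every
# cluster pair from scratch and merge the cheapest. Returns the partition
# after each merge plus the merge heights.
naive_ward_oracle <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), identity)
  heights <- numeric(0)
  partitions <- list()
  cost <- function(A, B) {
    mA <- colMeans(X[A, , drop = FALSE])
    mB <- colMeans(X[B, , drop = FALSE])
    sqrt(2 * length(A) * length(B) / (length(A) + length(B)) *
           sum((mA - mB)^2))
  }
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          cc <- cost(clusters[[i]], clusters[[j]])
          if (cc < best[1]) best <- c(cc, i, j)
        }
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    partitions <- c(partitions, list(lapply(clusters, sort)))
  }
  list(heights = heights, partitions = partitions)
}

# Canonical string form of a partition (list of index vectors), invariant
# to cluster order and within-cluster order.
canonical_partition <- function(part) {
  s <- sort(vapply(part, function(cl) paste(sort(cl), collapse = ","),
                   character(1)))
  paste(s, collapse = "|")
}

# Partition after each merge of an hclust object.
hclust_partitions <- function(hc, n) {
  lapply(seq_len(n - 1), function(s) {
    split(seq_len(n), stats::cutree(hc, k = n - s))
  })
}

# Distance correlation by explicit double-centering (loops, no row-sum
# shortcut).
naive_dcor_oracle <- function(x, y) {
  n <- length(x)
  center <- function(m) {
    A <- matrix(0, n, n)
    rm_ <- rowMeans(m)
    cm <- colMeans(m)
    gm <- mean(m)
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        A[j, k] <- m[j, k] - rm_[j] - cm[k] + gm
      }
    }
    A
  }
  A <- center(abs(outer(x, x, "-")))
  B <- center(abs(outer(y, y, "-")))
  dcov2 <- mean(A * B)
  vx <- mean(A * A)
  vy <- mean(B * B)
  if (vx <= 0 || vy <= 0) return(0)
  sqrt(max(0, min(1, dcov2 / sqrt(vx * vy))))
}

# Independent CV accuracy: per-fold z-scoring by the training fold's mean
# and population SD, 1-nearest-neighbour (Euclidean, lowest-index tie)
# prediction of the held-out fold.
oracle_cv_acc_1nn <- function(X, y, subset_idx, fold_ids) {
  if (!length(subset_idx)) return(max(table(y)) / length(y))
  Xs <- X[, subset_idx, drop = FALSE]
  correct <- 0
  for (f in sort(unique(fold_ids))) {
    te <- which(fold_ids == f)
    tr <- which(fold_ids != f)
    Xtr <- Xs[tr, , drop = FALSE]
    Xte <- Xs[te, , drop = FALSE]
    for (j in seq_len(ncol(Xtr))) {
      m <- mean(Xtr[, j])
      s <- sqrt(mean((Xtr[, j] - m)^2))
      if (s > 0) {
        Xtr[, j] <- (Xtr[, j] - m) / s
        Xte[, j] <- (Xte[, j] - m) / s
      }
    }
    for (i in seq_along(te)) {
      d2 <- rowSums((Xtr - matrix(Xte[i, ], nrow(Xtr), ncol(Xtr),
                                  byrow = TRUE))^2)
      nn <- which.min(d2)
      correct <- correct + (y[tr][nn] == y[te][i])
    }
  }
  correct / length(y)
}

# Step-by-step exhaustive forward search with the 1-NN oracle above:
# candidates visited in descending Fisher score (own formula), accepted
# iff CV accuracy strictly increases.
oracle_forward_1nn <- function(X, y, seed_idx, fold_ids) {
  fisher <- function(v) {
    mu <- mean(v)
    num <- den <- 0
    for (cl in unique(y)) {
      vc <- v[y == cl]
      num <- num + length(vc) * (mean(vc) - mu)^2
      den <- den + length(vc) * mean((vc - mean(vc))^2)
    }
    if (den == 0) 0 else num / den
  }
  pool <- setdiff(seq_len(ncol(X)), seed_idx)
  fs <- vapply(pool, function(j) fisher(X[, j]), numeric(1))
  pool <- pool[order(-fs, pool)]
  current <- seed_idx
  acc <- oracle_cv_acc_1nn(X, y, current, fold_ids)
  trace <- list(c(length(current), acc))
  for (cand in pool) {
    acc_new <- oracle_cv_acc_1nn(X, y, c(current, cand), fold_ids)
    if (acc_new > acc) {
      current <- c(current, cand)
      acc <- acc_new
      trace <- c(trace, list(c(length(current), acc)))
    }
  }
  list(subset = current, accuracy = acc, trace = trace)
}
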