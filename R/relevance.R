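#' Fisher score of one feature
#'
#' Ratio of between-class to within-class scatter,
#' \deqn{FS = \sum_c n_c (\mu_c - \mu)^2 / \sum_c n_c \sigma_c^2,}
#' with class means \eqn{\mu_c}, overall mean \eqn{\mu}, class sizes
#' \eqn{n_c} and class *population* variances \eqn{\sigma_c^2} (1/n_c
#' denominator, so the value is an exact, documented constant of the data).
#' Higher means more discriminative. A constant feature scores 0;
#' perfectly separated constant classes (zero denominator, positive
#' numerator) are an error.
#'
#' @param x numeric vector.
#' @param y binary 0/1 labels, both classes non-empty.
#' @return non-negative Fisher score.
#' @export
fisher_score <- function(x, y) {
  ok <- !is.na(x)
  x <- x[ok]
  y <- y[ok]
  classes <- sort(unique(y))
  if (length(classes) != 2L) stop("both classes must be non-empty")
  mu <- mean(x)
  num <- 0
  den <- 0
  for (cl in classes) {
    xc <- x[y == cl]
    nc <- length(xc)
    num <- num + nc * (mean(xc) - mu)^2
    den <- den + nc * mean((xc - mean(xc))^2)
  }
  if (den == 0) {
    if (num == 0) return(0)
    stop("zero within-class variance with separated class means: score is infinite")
  }
  num / den
}

#' Relief-F feature weights
#'
#' Instance-based feature weighting: for each of `m` sampled instances the
#' weight of feature `f` moves up by its difference to the `k` nearest
#' misses (other class) and down by its difference to the `k` nearest hits
#' (same class), averaged over `m * k`. Differences are range-normalized
#' `|a - b| / range` for numeric features and 0/1 indicators for
#' categorical/binary ones; neighbor distance is the Manhattan sum of the
#' same differences. Ties in neighbor distance are broken by sample index,
#' so the result is a deterministic function of `(table, k, m, seed)`.
#'
#' @param table a complete [feature_table()].
#' @param k neighbors per class (default 10; must not exceed the smaller
#'   class size minus 1 — [rank_features()] caps its default at that bound).
#' @param m instances to sample (default all, in which case every instance
#'   is used once).
#' @param seed integer seed for the instance sample.
#' @return a `score_vector` (method `"R_F"`); weights lie in `[-1, 1]`.
#' @export
relief_f <- function(table, k = 10L, m = NULL, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$values
  if (anyNA(X)) stop("relief_f requires a complete table (impute first)")
  y <- table$labels
  n <- nrow(X)
  p <- ncol(X)
  min_class <- min(table(y))
  k <- as.integer(k)
  if (k < 1L || k > min_class - 1L) {
    stop("k must be at least 1 and at most the smaller class size - 1")
  }
  # per-feature normalized difference matrix ingredients
  rng <- apply(X, 2, function(col) diff(range(col)))
  is_num <- table$meta$kind == "numeric"
  diff_cell <- function(i, idx) {
    # |p|-col matrix of normalized diffs between instance i and rows idx
    d <- abs(X[idx, , drop = FALSE] -
               matrix(X[i, ], length(idx), p, byrow = TRUE))
    for (j in seq_len(p)) {
      if (is_num[j]) {
        d[, j] <- if (rng[j] == 0) 0 else d[, j] / rng[j]
      } else {
        d[, j] <- as.numeric(d[, j] != 0)
      }
    }
    d
  }
  use <- if (is.null(m) || m >= n) {
    seq_len(n)
  } else {
    with_seed(seed, sample(n, m))
  }
  m_eff <- length(use)
  w <- numeric(p)
  for (i in use) {
    d <- diff_cell(i, seq_len(n))
    dist_i <- rowSums(d)
    dist_i[i] <- Inf
    hits <- which(y == y[i])
    misses <- which(y != y[i])
    near <- function(idx) idx[order(dist_i[idx], idx)[seq_len(k)]]
    nh <- near(hits[hits != i])
    nm <- near(misses)
    w <- w + colSums(d[nm, , drop = FALSE]) - colSums(d[nh, , drop = FALSE])
  }
  scores <- w / (m_eff * k)
  names(scores) <- table$meta$name
  score_vector("R_F", scores, params = list(k = k, m = m_eff, seed = seed))
}

#' Plug-in mutual information between a feature and the label
#'
#' Mutual information (nats) of the discretized joint distribution
#' `sum p(a,b) log[p(a,b) / (p(a) p(b))]`. Numeric features are cut into
#' `bins` equal-frequency bins (quantile breaks, duplicates collapsed);
#' categorical/binary features are used as-is.
#'
#' @param x feature vector.
#' @param y binary labels.
#' @param bins number of bins for numeric `x` (default 10).
#' @param numeric_x treat `x` as numeric and discretize (default guesses
#'   from the number of distinct values).
#' @return non-negative mutual information in nats.
#' @export
mutual_information <- function(x, y, bins = 10L,
                               numeric_x = length(unique(x)) > 10L) {
  ok <- !is.na(x)
  x <- x[ok]
  y <- y[ok]
  if (!length(x)) stop("empty input")
  if (numeric_x) {
    if (bins < 2L) stop("bins must be >= 2")
    brk <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
    x <- if (length(brk) < 2L) rep(1L, length(x)) else {
      cut(x, breaks = brk, include.lowest = TRUE, labels = FALSE)
    }
  }
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  terms <- joint * log(joint / outer(px, py))
  max(0, sum(terms[joint > 0]))
}

#' Distance correlation (dCor)
#'
#' Szekely's sample distance correlation between two numeric vectors:
#' double-centered pairwise Euclidean distance matrices, with
#' `dCor = dCov / sqrt(dVar_x dVar_y)`, computed here through the row-sum
#' identity `dCov^2 = S1 - 2 S2 + S3`. Lies in `[0, 1]`; defined as 0 when
#' either marginal distance variance vanishes (constant input).
#'
#' @param x,y numeric vectors of equal length `n >= 2`.
#' @return distance correlation in `[0, 1]`.
#' @export
distance_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 paired observations")
  a <- abs(outer(x, x, "-"))
  b <- abs(outer(y, y, "-"))
  dcov2 <- function(a, b) {
    s1 <- sum(a * b) / n^2
    s2 <- sum(rowSums(a) * rowSums(b)) / n^3
    s3 <- sum(a) * sum(b) / n^4
    s1 - 2 * s2 + s3
  }
  vx <- dcov2(a, a)
  vy <- dcov2(b, b)
  if (vx <= 0 || vy <= 0) return(0)
  r2 <- dcov2(a, b) / sqrt(vx * vy)
  sqrt(max(0, min(1, r2)))
}

#' Score vector container
#'
#' @param method one of `"FS"`, `"R_F"`, `"MI"`, `"DCFS"`.
#' @param scores named numeric vector, one score per feature.
#' @param params list of method settings used.
#' @return object of class `score_vector`.
#' @export
score_vector <- function(method, scores, params = list()) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  structure(list(method = method, scores = scores, params = params),
            class = "score_vector")
}

#' @method print score_vector
#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("<score_vector> method %s, %d features\n",
              x$method, length(x$scores)))
  print(utils::head(sort(x$scores, decreasing = TRUE), 10))
  invisible(x)
}

#' Rank all features of a table by a relevance measure
#'
#' Computes one relevance score per feature and returns them in descending
#' order, ties broken by original column order. `"FS"` is the Fisher
#' score, `"R_F"` Relief-F, `"MI"` plug-in mutual information against the
#' label, `"DCFS"` distance correlation against the label (categorical
#' codes used as ordinal numerics, as in the source cohort's convention).
#'
#' @param table a complete [feature_table()].
#' @param method one of `"FS"`, `"R_F"`, `"MI"`, `"DCFS"`.
#' @param bins MI discretization bins.
#' @param k,m,seed Relief-F settings (see [relief_f()]).
#' @return a `score_vector` with scores sorted in rank order.
#' @export
rank_features <- function(table, method = c("FS", "R_F", "MI", "DCFS"),
                          bins = 10L, k = 10L, m = NULL, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  method <- match.arg(method)
  y <- table$labels
  sv <- switch(
    method,
    FS = {
      s <- apply(table$values, 2, fisher_score, y = y)
      score_vector("FS", s)
    },
    R_F = relief_f(table, k = min(k, min(table(y)) - 1L), m = m, seed = seed),
    MI = {
      s <- vapply(seq_len(ncol(table$values)), function(j) {
        mutual_information(table$values[, j], y, bins = bins,
                           numeric_x = table$meta$kind[j] == "numeric")
      }, numeric(1))
      names(s) <- table$meta$name
      score_vector("MI", s, params = list(bins = bins))
    },
    DCFS = {
      s <- apply(table$values, 2, distance_correlation, y = as.numeric(y))
      score_vector("DCFS", s)
    }
  )
  # stable sort: descending score, ties by original column order
  ord <- order(-sv$scores[table$meta$name])
  sv$scores <- sv$scores[table$meta$name][ord]
  sv
}

#' Top-k feature names of a ranking
#'
#' @param ranking a `score_vector` from [rank_features()].
#' @param k subset size.
#' @return character vector of the k highest-scoring feature names.
#' @export
top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "score_vector"), k >= 1,
            k <= length(ranking$scores))
  names(ranking$scores)[seq_len(k)]
}
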