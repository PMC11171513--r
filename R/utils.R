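# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded generators are pure
#' functions of their arguments and never perturb the caller's stream.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Stratified k-fold partition
#'
#' Assigns every sample to one of `k` folds, keeping the class ratio of
#' `labels` as balanced as integer arithmetic allows. Deterministic given
#' `seed`.
#'
#' @param labels binary 0/1 vector.
#' @param k number of folds (>= 2).
#' @param seed integer seed fixing the shuffle.
#' @return integer vector of fold ids in `1..k`, same length as `labels`.
#' @export
stratified_folds <- function(labels, k, seed) {
  stopifnot(k >= 2)
  n <- length(labels)
  if (min(table(labels)) < k) {
    stop("fold count exceeds the size of the smaller class")
  }
  fold <- integer(n)
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Population standard deviation (1/n denominator).
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name))
  }
}
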