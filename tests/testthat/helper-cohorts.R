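# Fixture builders shared across test files. Everything is generated in
# code under explicit seeds; nothing is read from disk.

# Two-group cohort with n_inf informative numeric features (group-1 mean
# shifted by Cohen's d) and n_noise pure-noise features.
planted_spec <- function(n_inf = 6, n_noise = 14, d = 0.6, n = 339) {
  feats <- c(
    lapply(seq_len(n_inf), function(i) {
      feature_spec(paste0("inf", i), "numeric", c(0, 1), c(d, 1))
    }),
    lapply(seq_len(n_noise), function(i) {
      feature_spec(paste0("noise", i), "numeric", c(0, 1), c(0, 1))
    })
  )
  cohort_spec(feats, n_per_group = n, missing_rate = 0)
}

# Small hand-built numeric table.
tiny_table <- function(values, labels, kinds = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  kinds <- kinds %||% rep("numeric", ncol(values))
  feature_table(values, labels,
                data.frame(name = colnames(values), kind = kinds,
                           n_levels = NA_integer_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
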