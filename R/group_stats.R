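#' Two-sample t statistic from printed summaries
#'
#' Welch's unequal-variance t computed directly from per-group
#' `(mean, sd, n)` summaries, as printed in cohort overview tables:
#' \deqn{t = (m_0 - m_1) / \sqrt{s_0^2/n_0 + s_1^2/n_1}}
#' with Welch–Satterthwaite degrees of freedom and a two-sided p-value.
#' With equal group sizes the statistic coincides with the pooled-SE form.
#'
#' @param mean0,sd0,n0 summary of group 0.
#' @param mean1,sd1,n1 summary of group 1.
#' @return list with `t`, `df`, `p`.
#' @export
t_from_summary <- function(mean0, sd0, n0, mean1, sd1, n1) {
  stopifnot(n0 >= 2, n1 >= 2, sd0 >= 0, sd1 >= 0)
  v0 <- sd0^2 / n0
  v1 <- sd1^2 / n1
  if (v0 + v1 == 0) {
    if (mean0 == mean1) {
      return(list(t = 0, df = n0 + n1 - 2, p = 1))
    }
    stop("both groups have zero variance but different means: t is infinite")
  }
  t <- (mean0 - mean1) / sqrt(v0 + v1)
  df <- (v0 + v1)^2 / (v0^2 / (n0 - 1) + v1^2 / (n1 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Welch t-test on raw group vectors
#'
#' Thin wrapper around [stats::t.test()] (Welch); by construction it agrees
#' with [t_from_summary()] applied to the groups' own sample summaries.
#'
#' @param x0,x1 numeric vectors, one per group, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
t_test_raw <- function(x0, x1) {
  x0 <- x0[!is.na(x0)]
  x1 <- x1[!is.na(x1)]
  if (length(x0) < 2 || length(x1) < 2) {
    stop("each group needs at least 2 observations")
  }
  if (stats::sd(x0) == 0 && stats::sd(x1) == 0) {
    return(t_from_summary(mean(x0), 0, length(x0), mean(x1), 0, length(x1)))
  }
  ht <- stats::t.test(x0, x1, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pearson chi-square test on a contingency table
#'
#' Uncorrected chi-square statistic `sum((O-E)^2/E)` with expected counts
#' from the row/column margins; no continuity correction (the convention
#' used by the cohort overview this package reproduces).
#'
#' @param counts matrix of non-negative counts, at least 2 rows and 2
#'   columns.
#' @return list with `chi2`, `df`, `p`.
#' @export
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("contingency table needs at least 2 rows and 2 columns")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero margin: every row and column must contain observations")
  }
  expected <- outer(rs, cs) / sum(counts)
  chi2 <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Per-feature group comparison report
#'
#' Reproduces the structure of a clinical cohort overview table: for each
#' numeric feature the per-group mean +/- SD and a Welch t-test; for each
#' categorical or binary feature the per-group level counts and a
#' chi-square test. Missing cells are dropped per feature.
#'
#' @param table a [feature_table()] with binary labels.
#' @param alpha significance level for the flag column (default 0.05).
#' @return data frame with one row per feature: `feature`, `kind`,
#'   `group0`, `group1` (formatted summaries), `statistic` (t or chi2),
#'   `df`, `p`, `significant`.
#' @export
table1_report <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  rows <- lapply(seq_len(ncol(table$values)), function(j) {
    x <- table$values[, j]
    kind <- table$meta$kind[j]
    g0 <- x[table$labels == 0L]
    g1 <- x[table$labels == 1L]
    if (kind == "numeric") {
      res <- t_test_raw(g0, g1)
      data.frame(
        feature = table$meta$name[j], kind = kind,
        group0 = sprintf("%.2f ± %.2f", mean(g0, na.rm = TRUE),
                         stats::sd(g0, na.rm = TRUE)),
        group1 = sprintf("%.2f ± %.2f", mean(g1, na.rm = TRUE),
                         stats::sd(g1, na.rm = TRUE)),
        statistic = res$t, df = res$df, p = res$p,
        stringsAsFactors = FALSE
      )
    } else {
      lv <- sort(unique(x[!is.na(x)]))
      counts <- cbind(
        vapply(lv, function(l) sum(g0 == l, na.rm = TRUE), numeric(1)),
        vapply(lv, function(l) sum(g1 == l, na.rm = TRUE), numeric(1))
      )
      res <- chi_square(counts)
      fmt <- function(cnt) {
        paste(sprintf("%d (%.1f%%)", cnt, 100 * cnt / sum(cnt)),
              collapse = ", ")
      }
      data.frame(
        feature = table$meta$name[j], kind = kind,
        group0 = fmt(counts[, 1]), group1 = fmt(counts[, 2]),
        statistic = res$chi2, df = res$df, p = res$p,
        stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha
  out
}
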