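#' Generate a synthetic two-group cohort
#'
#' Draws a balanced two-class [feature_table()] from a [cohort_spec()].
#' Numeric features are Gaussian with the group's mean/SD; categorical and
#' binary features are drawn from the group's probabilities. Features
#' sharing a correlation block are coupled per group through a Gaussian
#' copula with an equicorrelated latent (common factor plus idiosyncratic
#' noise), so the printed marginal moments are preserved exactly.
#'
#' A numeric `lower_bound` is enforced by redrawing the offending cell's
#' latent draw until the bound is met (truncated-normal marginal, no point
#' mass at the bound); the redraw is independent, so coupling is lost only
#' for the redrawn cells. If `spec$missing_rate > 0`, missingness is
#' injected with [inject_missing()] under a seed derived from `seed`.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; identical `(spec, seed)` give bit-identical
#'   tables.
#' @return a [feature_table()] with `2 * n_per_group` rows, group 0 first.
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_per_group
  p <- length(spec$features)
  blocks <- vapply(spec$features, `[[`, character(1), "block")
  kinds <- vapply(spec$features, `[[`, character(1), "kind")
  rho <- spec$block_correlation
  bad <- setdiff(stats::na.omit(unique(blocks)), c(names(rho), NA))
  # blocks with no declared correlation default to independence
  values <- with_seed(seed, {
    draw_group <- function(which_group) {
      z <- matrix(stats::rnorm(n * p), n, p)
      for (b in names(rho)) {
        members <- which(!is.na(blocks) & blocks == b)
        if (length(members) >= 2L && rho[[b]] > 0) {
          g <- stats::rnorm(n)
          z[, members] <- sqrt(rho[[b]]) * g +
            sqrt(1 - rho[[b]]) * z[, members]
        }
      }
      out <- matrix(NA_real_, n, p)
      for (j in seq_len(p)) {
        fs <- spec$features[[j]]
        par <- if (which_group == 0L) fs$group0 else fs$group1
        if (fs$kind == "numeric") {
          x <- par[1] + par[2] * z[, j]
          if (!is.null(fs$lower_bound)) {
            if (par[2] == 0 && par[1] < fs$lower_bound) {
              stop(fs$name, ": constant value below its lower bound")
            }
            while (any(viol <- x < fs$lower_bound)) {
              x[viol] <- par[1] + par[2] * stats::rnorm(sum(viol))
            }
          }
          out[, j] <- x
        } else if (fs$kind == "categorical") {
          breaks <- c(0, cumsum(par))
          breaks[length(breaks)] <- 1
          out[, j] <- as.numeric(cut(stats::pnorm(z[, j]), breaks = breaks,
                                     labels = FALSE, include.lowest = TRUE))
        } else { # binary: large latent -> 1, keeps block coupling positive
          out[, j] <- as.numeric(stats::pnorm(z[, j]) > 1 - par)
        }
      }
      out
    }
    rbind(draw_group(0L), draw_group(1L))
  })
  meta <- data.frame(
    name = names(spec$features),
    kind = kinds,
    n_levels = vapply(spec$features, function(f) {
      if (f$kind == "categorical") length(f$group0) else NA_integer_
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  tab <- feature_table(values, rep(c(0L, 1L), each = n), meta,
                       label_name = spec$label_name)
  if (spec$missing_rate > 0) {
    tab <- inject_missing(tab, spec$missing_rate,
                          seed = (as.integer(seed) + 999983L) %% 2147483647L)
  }
  tab
}

#' Mask feature cells at random
#'
#' Each feature cell is masked (set to `NA`) independently with probability
#' `rate`; labels are never masked.
#'
#' @param table a [feature_table()].
#' @param rate masking probability in `[0, 1)`.
#' @param seed integer seed; the mask is a pure function of
#'   `(table dim, rate, seed)`.
#' @return the table with additional `NA` cells.
#' @export
inject_missing <- function(table, rate, seed) {
  stopifnot(inherits(table, "feature_table"))
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(table)
  if (rate > 0.5) {
    warning("missing rate ", rate, " will leave few observed cells")
  }
  mask <- with_seed(seed, {
    matrix(stats::runif(length(table$values)) < rate,
           nrow(table$values), ncol(table$values))
  })
  values <- table$values
  values[mask] <- NA_real_
  feature_table(values, table$labels, table$meta, table$label_name)
}
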