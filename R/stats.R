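#' Kruskal-Wallis one-way analysis of variance on ranks
#'
#' Rank-based H statistic with tie correction and a chi-square reference
#' distribution on `k - 1` degrees of freedom (delegates to
#' [stats::kruskal.test()]). The degenerate case of identical values in every
#' group returns `H = 0, p = 1`.
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @return object of class `stat_result`: list with `H`, `df`, `p_value`,
#'   `n_per_group`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups")
  if (any(lengths(groups) == 0)) stop("every group must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L) {
    res <- list(H = 0, df = length(groups) - 1L, p_value = 1,
                n_per_group = lengths(groups))
  } else {
    kt <- kruskal.test(x, g)
    res <- list(H = unname(kt$statistic), df = unname(kt$parameter),
                p_value = kt$p.value, n_per_group = lengths(groups))
  }
  class(res) <- "stat_result"
  res
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g (n = %s)\n",
              x$H, x$df, x$p_value,
              paste(x$n_per_group, collapse = ", ")))
  invisible(x)
}

#' Dunn's multiple-comparison post-hoc test
#'
#' Pairwise z statistics from mean-rank differences using the tie-corrected
#' pooled variance
#' `sigma_ij^2 = (N(N+1)/12 - sum(t^3 - t)/(12(N-1))) * (1/n_i + 1/n_j)`
#' over the joint ranking of all groups, with family-wise adjustment of the
#' two-sided p-values across all pairs (Holm by default).
#'
#' @param groups list of >= 2 non-empty numeric vectors (the same groups the
#'   Kruskal-Wallis test was run on).
#' @param adjust p-value adjustment method (see [stats::p.adjust()]).
#' @return data.frame with `group_a`, `group_b`, `z`, `p_value`,
#'   `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, adjust = "holm") {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups")
  if (any(lengths(groups) == 0)) stop("every group must be non-empty")
  k <- length(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lengths(groups))
  N <- length(x)
  r <- rank(x)
  mean_ranks <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_term
  n <- lengths(groups)
  pairs <- utils::combn(k, 2)
  z <- p <- numeric(ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]; j <- pairs[2, q]
    se <- sqrt(base_var * (1 / n[i] + 1 / n[j]))
    z[q] <- if (se == 0) 0 else (mean_ranks[i] - mean_ranks[j]) / se
    p[q] <- 2 * stats::pnorm(-abs(z[q]))
  }
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
             z = z, p_value = p,
             p_adjusted = p.adjust(p, method = adjust))
}
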