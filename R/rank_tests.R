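#' Two-sided Wilcoxon rank-sum test
#'
#' Thin wrapper around [stats::wilcox.test()] with the conventions used
#' throughout the analyses: midranks for ties, the exact null distribution
#' for small tie-free samples (n <= 10 per group), and the normal
#' approximation with tie correction otherwise. Constant pooled data give
#' p = 1.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @return List: `statistic` (rank-sum W of `x`), `p`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) fail("both samples need >= 2 values")
  if (stats::var(c(x, y)) == 0)
    return(list(statistic = NA_real_, p = 1, method = "degenerate"))
  exact <- length(x) <= 10 && length(y) <= 10 &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(statistic = unname(wt$statistic), p = wt$p.value, method = wt$method)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks with pairwise-complete handling of
#' missing values; permutation-exact p for n <= 9 (tie-free), t
#' approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length (n >= 3 complete pairs).
#' @return List: `rho`, `p`, `n` (complete pairs).
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) fail("need >= 3 complete pairs")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(x),
                degenerate = TRUE))
  exact <- length(x) <= 9 && !any(duplicated(x)) && !any(duplicated(y))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = exact))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
       degenerate = FALSE)
}
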