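#' Subwindow permutation analysis (SPA) variable selection
#'
#' Monte Carlo variable selection for PLS-DA: each round trains a PLS-DA
#' model on a random subject subset (stratified, default 70%) and a random
#' variable subwindow (default half the candidates, at least 2), recording
#' the out-of-subset misclassification error. Per variable, the error
#' distributions of rounds that included versus excluded it are compared
#' with a one-sided rank-sum test (inclusion lowers the error for an
#' informative variable); variables with p below `alpha` are selected. The
#' whole procedure is repeated on the selected set until two successive
#' passes return the identical set (at most `max_iter` passes).
#'
#' @param X Predictor matrix (>= 2 columns, named).
#' @param y Two-class response (factor or +1/-1).
#' @param n_mc Monte Carlo rounds per pass (default 10000).
#' @param subset_frac Fraction of subjects per round (default 0.7).
#' @param var_frac Fraction of candidate variables per round (default 0.5,
#'   minimum 2 variables).
#' @param ncomp PLS components (default 3).
#' @param alpha Selection level (default 0.05).
#' @param max_iter Maximum stabilization passes (default 10).
#' @param seed Integer seed.
#' @return Character vector of selected variable names (possibly empty,
#'   with a warning); attributes `p_values` (last pass) and `n_passes`.
#' @export
spa_select <- function(X, y, n_mc = 10000, subset_frac = 0.7,
                       var_frac = 0.5, ncomp = 3, alpha = 0.05,
                       max_iter = 10, seed = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (ncol(X) < 2) fail("need >= 2 candidate variables")
  if (is.factor(y)) y <- ifelse(y == levels(y)[1], -1, 1)
  y <- sign(as.numeric(y))
  with_seed(seed, {
    current <- colnames(X)
    prev <- NULL
    n_passes <- 0L
    pvals <- NULL
    # a set of <= 2 variables cannot be subwindowed further (every round
    # would include all of it, leaving no exclusion group to compare
    # against) and is treated as stable
    while (n_passes < max_iter && !identical(sort(current), sort(prev)) &&
           length(current) >= 3) {
      prev <- current
      n_passes <- n_passes + 1L
      Xc <- X[, current, drop = FALSE]
      pvals <- spa_pass(Xc, y, n_mc, subset_frac, var_frac, ncomp)
      sel <- names(pvals)[pvals < alpha]
      if (length(sel) == 0) { current <- character(0); break }
      current <- sel
    }
    if (length(current) == 0)
      warning("SPA selected no variables")
    attr(current, "p_values") <- pvals
    attr(current, "n_passes") <- n_passes
    current
  })
}

# One SPA pass: n_mc subwindow rounds over the given candidates.
#
# The candidate pool is augmented with one "shadow" variable per
# candidate (a row-permuted copy, hence null by construction but with the
# same marginal distribution). The per-variable one-sided rank-sum
# z-statistic (inclusion lowers the error) is then calibrated against
# the shadow statistics: a noise variable whose realized sample
# correlation with the labels happens to help prediction produces the
# same kind of statistic as a shadow, so thresholding at the shadow
# alpha-quantile controls the per-variable false-selection rate — the
# raw rank-sum p-value does not, because with many Monte Carlo rounds
# any realized chance correlation becomes "significant".
spa_pass <- function(X, y, n_mc, subset_frac, var_frac, ncomp) {
  n <- nrow(X); p <- ncol(X)
  Xsh <- cbind(apply(X, 2, sample), apply(X, 2, sample))
  colnames(Xsh) <- paste0(".shadow.", seq_len(2 * p))
  Xa <- cbind(X, Xsh)
  pa <- ncol(Xa)
  nv <- max(2L, round(var_frac * p))
  i_pos <- which(y > 0); i_neg <- which(y <= 0)
  n_pos <- max(2L, round(subset_frac * length(i_pos)))
  n_neg <- max(2L, round(subset_frac * length(i_neg)))
  errs <- numeric(n_mc)
  inc <- matrix(FALSE, n_mc, pa, dimnames = list(NULL, colnames(Xa)))
  for (r in seq_len(n_mc)) {
    vars <- sample.int(pa, nv)
    train <- c(sample(i_pos, n_pos), sample(i_neg, n_neg))
    test <- setdiff(seq_len(n), train)
    if (length(test) < 2) { errs[r] <- NA; next }
    fit <- pls_fit(Xa[train, vars, drop = FALSE], y[train], ncomp = ncomp)
    pred <- predict(fit, Xa[test, vars, drop = FALSE])
    errs[r] <- mean(sign(pred) != sign(y[test]))
    inc[r, vars] <- TRUE
  }
  ok <- which(is.finite(errs))
  rk <- rank(errs[ok])
  zstat <- vapply(seq_len(pa), function(j) {
    in_j <- inc[ok, j]
    n1 <- sum(in_j); n2 <- sum(!in_j)
    if (n1 < 2 || n2 < 2) return(0)
    u <- sum(rk[in_j]) - n1 * (n1 + 1) / 2
    (u - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  }, numeric(1))
  z_real <- zstat[seq_len(p)]
  z_sh <- zstat[(p + 1):pa]
  m <- length(z_sh)
  mu <- mean(z_sh); s <- max(stats::sd(z_sh), 1e-6)
  # t-calibration accounts for estimating the shadow null from m shadows
  pv <- stats::pt((z_real - mu) / (s * sqrt(1 + 1 / m)), df = m - 1)
  names(pv) <- colnames(X)
  pv
}
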