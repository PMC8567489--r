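#' Construct a pore-size distribution object
#'
#' @param d_grid Diameter grid (um), sorted increasing (log-spaced by
#'   convention).
#' @param density Probability density over the grid (1/um); normalized to
#'   integrate to one.
#' @param areal_density Areal pore density scale (pores/mm^2).
#' @return Object of class `pore_size_distribution`.
#' @export
new_pore_size_distribution <- function(d_grid, density, areal_density = 1) {
  stopifnot(length(d_grid) == length(density), all(density >= 0),
            !is.unsorted(d_grid))
  w <- grid_weights(d_grid)
  tot <- sum(density * w)
  if (tot <= 0) fail("density integrates to zero")
  structure(list(d_grid = d_grid, density = density / tot,
                 areal_density = areal_density),
            class = "pore_size_distribution")
}

#' Default inversion configuration
#'
#' @param lambda Regularization weight for the second-difference smoothness
#'   penalty; `"auto"` selects it by the discrepancy principle against the
#'   estimated BSC noise, a fixed number gives reproducible fixed-lambda
#'   inversions.
#' @param d_min,d_max,n_d Diameter grid bounds (um) and size; the default
#'   64 log-spaced bins over 5-400 um span Haversian to "giant" pores.
#' @param noise_frac Assumed relative BSC noise used by the discrepancy
#'   principle when no noise estimate accompanies the data.
#' @return List of class `inversion_config`.
#' @export
inversion_config <- function(lambda = "auto", d_min = 5, d_max = 400,
                             n_d = 64, noise_frac = 0.05) {
  if (is.numeric(lambda) && lambda < 0) fail("lambda must be >= 0")
  stopifnot(d_min > 0, d_max > d_min, n_d >= 8)
  structure(list(lambda = lambda, d_min = d_min, d_max = d_max,
                 n_d = as.integer(n_d), noise_frac = noise_frac),
            class = "inversion_config")
}

#' Invert a pore-size distribution from a backscatter coefficient
#'
#' Solves the regularized non-negative least-squares problem
#' \deqn{\min_{u \ge 0} \| K u - BSC \|^2 + \lambda \| D_2 (u/\Delta d) \|^2}
#' where `u_j = s p(d_j) \Delta d_j` is the per-bin scattering mass,
#' `D_2` the second-difference operator on the density, and the free scale
#' `s` becomes the areal pore density. Multiplying the BSC by a positive
#' constant rescales `s` only; the normalized density and all descriptors
#' are scale-invariant.
#'
#' @param bsc A [estimate_bsc()] `bsc_result`, or a list with numeric
#'   `spectrum$frequency` and `spectrum$bsc`.
#' @param kernel A [build_kernel()] kernel on the same frequency grid.
#' @param cfg An [inversion_config()].
#' @return A `pore_size_distribution` with descriptor list in
#'   `$descriptors` (see [describe_distribution()]), the residual norm, and
#'   the lambda used.
#' @export
invert_distribution <- function(bsc, kernel, cfg = inversion_config()) {
  stopifnot(inherits(kernel, "bsc_kernel"))
  b <- bsc$spectrum$bsc
  fb <- bsc$spectrum$frequency
  if (length(fb) != length(kernel$f_grid) ||
      max(abs(fb - kernel$f_grid)) > 1e-9)
    fail("BSC frequency grid does not match the kernel grid")
  if (sum(b > 0) < 10)
    fail("no signal: BSC positive on fewer than 10 frequencies")
  K <- kernel$K
  d <- kernel$d_grid
  nd <- length(d)
  w <- grid_weights(d)
  # second differences of the density u / delta_d, with first-difference
  # rows at both grid ends (an edge bin has no second difference, which
  # would otherwise leave boundary spikes unpenalized)
  D2 <- matrix(0, nd, nd)
  for (i in seq_len(nd - 2))
    D2[i, i:(i + 2)] <- c(1, -2, 1)
  D2[nd - 1, 1:2] <- c(1, -1)
  D2[nd, (nd - 1):nd] <- c(-1, 1)
  Dd <- D2 %*% diag(1 / w)
  Dd <- Dd / sqrt(mean(Dd^2))
  # light ridge on the density damps mass in diameter bins the kernel is
  # insensitive to (their columns are ~0, so without it NNLS can park
  # arbitrary probability mass there to fit systematic residuals)
  Rg <- diag(1 / w)
  Rg <- Rg / sqrt(mean(Rg^2))
  scale_K <- sqrt(mean(K^2))
  noise <- sqrt(sum((cfg$noise_frac * b)^2))
  solve_lambda <- function(lam) {
    A <- rbind(K, sqrt(lam) * scale_K * Dd,
               sqrt(lam * 0.1) * scale_K * Rg)
    rhs <- c(b, numeric(2 * nd))
    fit <- pracma::lsqnonneg(A, rhs)
    u <- fit$x
    list(u = u, resid = sqrt(sum((K %*% u - b)^2)))
  }
  if (identical(cfg$lambda, "auto")) {
    # discrepancy principle: largest lambda whose residual stays within
    # the expected noise norm (residual grows monotonically with lambda)
    lams <- 10^seq(-8, 0, length.out = 17)
    sol <- solve_lambda(lams[1])
    lambda_used <- lams[1]
    for (lam in lams[-1]) {
      cand <- solve_lambda(lam)
      if (cand$resid <= noise) {
        sol <- cand; lambda_used <- lam
      } else break
    }
  } else {
    lambda_used <- cfg$lambda
    sol <- solve_lambda(cfg$lambda)
  }
  if (all(sol$u == 0)) fail("inversion returned the zero solution")
  s <- sum(sol$u)
  dist <- new_pore_size_distribution(d, (sol$u / s) / w, areal_density = s)
  dist$descriptors <- describe_distribution(dist)
  dist$lambda <- lambda_used
  dist$residual <- sol$resid
  dist
}

#' Descriptors of a pore-size distribution
#'
#' Peak position (argmax of the density, ties broken toward the smallest
#' diameter), Q10/Q90 quantiles by linear interpolation of the CDF, and the
#' outermost linear-interpolated crossings of half the peak density
#' (FWHM_min, FWHM_max, and their difference FWHM). All in um.
#'
#' @param dist A `pore_size_distribution`.
#' @return Named list: `peak`, `q10`, `q90`, `fwhm`, `fwhm_min`, `fwhm_max`.
#' @export
describe_distribution <- function(dist) {
  stopifnot(inherits(dist, "pore_size_distribution"))
  d <- dist$d_grid
  p <- dist$density
  if (max(p) - min(p) < 1e-12 * max(p, 1e-300))
    fail("no unique peak: density is flat")
  ipk <- which.max(p)                      # which.max takes the first tie
  peak <- d[ipk]
  # CDF by trapezoid, linear interpolation of quantiles
  cdf <- c(0, cumsum((p[-1] + p[-length(p)]) / 2 * diff(d)))
  cdf <- cdf / cdf[length(cdf)]
  qf <- function(q) {
    i <- findInterval(q, cdf, all.inside = TRUE)
    d[i] + (q - cdf[i]) / (cdf[i + 1] - cdf[i]) * (d[i + 1] - d[i])
  }
  half <- p[ipk] / 2
  above <- which(p >= half)
  lo <- min(above); hi <- max(above)
  fwhm_min <- if (lo == 1) d[1] else
    d[lo - 1] + (half - p[lo - 1]) / (p[lo] - p[lo - 1]) * (d[lo] - d[lo - 1])
  fwhm_max <- if (hi == length(p)) d[length(d)] else
    d[hi] + (p[hi] - half) / (p[hi] - p[hi + 1]) * (d[hi + 1] - d[hi])
  list(peak = peak, q10 = qf(0.1), q90 = qf(0.9),
       fwhm = fwhm_max - fwhm_min, fwhm_min = fwhm_min, fwhm_max = fwhm_max)
}

#' @export
print.pore_size_distribution <- function(x, ...) {
  de <- x$descriptors %||% describe_distribution(x)
  cat(sprintf("pore_size_distribution on [%.1f, %.1f] um (%d bins)\n",
              min(x$d_grid), max(x$d_grid), length(x$d_grid)))
  cat(sprintf("  Peak %.1f, Q10 %.1f, Q90 %.1f, FWHM %.1f um; scale %.2f pores/mm^2\n",
              de$peak, de$q10, de$q90, de$fwhm, x$areal_density))
  invisible(x)
}
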