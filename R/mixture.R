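#' Cortical pore-diameter mixture model
#'
#' Intracortical pore diameters are modeled as a two-component lognormal
#' mixture: a baseline component describing normally refilled Haversian
#' canals (median around 30 um) and an optional heavy tail describing
#' pathologically enlarged, merged remodeling cavities that can reach
#' several hundred um. With `tail_weight = 0` the model collapses to a
#' single lognormal.
#'
#' @param baseline_log_mean Log-mean (log um) of the baseline component.
#'   The default `log(30)` puts the baseline median at 30 um.
#' @param baseline_log_sd Log-SD of the baseline component.
#' @param tail_weight Mixture weight of the tail component, in `[0, 1]`.
#' @param tail_log_mean Log-mean (log um) of the tail component.
#' @param tail_log_sd Log-SD of the tail component.
#' @param pore_density Areal pore density (pores/mm^2).
#' @param hard_core Minimum center-to-center spacing (um) enforced when
#'   sampling pore positions.
#' @return Object of class `diameter_mixture`.
#' @export
diameter_mixture <- function(baseline_log_mean = log(30),
                             baseline_log_sd = 0.35,
                             tail_weight = 0.03,
                             tail_log_mean = log(120),
                             tail_log_sd = 0.40,
                             pore_density = 12,
                             hard_core = 80) {
  if (tail_weight < 0 || tail_weight > 1)
    fail("tail_weight must lie in [0, 1], got %g", tail_weight)
  if (baseline_log_sd <= 0 || tail_log_sd <= 0)
    fail("log-SDs must be positive")
  if (pore_density <= 0) fail("pore_density must be positive")
  if (hard_core < 0) fail("hard_core must be non-negative")
  structure(list(
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    tail_weight = tail_weight,
    tail_log_mean = tail_log_mean,
    tail_log_sd = tail_log_sd,
    pore_density = pore_density,
    hard_core = hard_core
  ), class = "diameter_mixture")
}

#' Mixture density, CDF, quantile function, and random draws
#'
#' @param x,q Diameters (um).
#' @param p Probabilities.
#' @param n Number of draws.
#' @param params A [diameter_mixture()] object.
#' @return Numeric vector.
#' @export
dmixture <- function(x, params) {
  w <- params$tail_weight
  (1 - w) * stats::dlnorm(x, params$baseline_log_mean, params$baseline_log_sd) +
    w * stats::dlnorm(x, params$tail_log_mean, params$tail_log_sd)
}

#' @rdname dmixture
#' @export
pmixture <- function(q, params) {
  w <- params$tail_weight
  (1 - w) * stats::plnorm(q, params$baseline_log_mean, params$baseline_log_sd) +
    w * stats::plnorm(q, params$tail_log_mean, params$tail_log_sd)
}

#' @rdname dmixture
#' @export
qmixture <- function(p, params) {
  stopifnot(all(p >= 0 & p <= 1))
  # numerical inversion of the mixture CDF (monotone bisection via uniroot)
  vapply(p, function(pp) {
    if (pp == 0) return(0)
    if (pp == 1) return(Inf)
    lo <- stats::qlnorm(pp, params$baseline_log_mean, params$baseline_log_sd)
    hi <- stats::qlnorm(pp, params$tail_log_mean, params$tail_log_sd)
    lim <- range(lo, hi)
    lim <- c(lim[1] * 0.5, lim[2] * 2 + 1)
    stats::uniroot(function(q) pmixture(q, params) - pp,
                   interval = lim, tol = 1e-10)$root
  }, numeric(1))
}

#' @rdname dmixture
#' @export
rmixture <- function(n, params, seed = NULL) {
  with_seed(seed, {
    from_tail <- stats::runif(n) < params$tail_weight
    d <- numeric(n)
    n_tail <- sum(from_tail)
    if (n_tail > 0)
      d[from_tail] <- stats::rlnorm(n_tail, params$tail_log_mean, params$tail_log_sd)
    if (n_tail < n)
      d[!from_tail] <- stats::rlnorm(n - n_tail, params$baseline_log_mean,
                                     params$baseline_log_sd)
    d
  })
}
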