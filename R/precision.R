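#' Short-term precision (RMS over subjects)
#'
#' Root-mean-square within-subject precision over m subjects with k
#' repeated measurements each:
#' absolute precision \eqn{\sqrt{\sum_j SD_j^2 / m}} (parameter units) and
#' relative precision \eqn{100 \sqrt{\sum_j (SD_j/\bar{x}_j)^2 / m}} (%,
#' the RMS coefficient of variation).
#'
#' @param repeats Numeric matrix (subjects x repeats) or data frame.
#' @return Object of class `precision_result`: `absolute`, `relative_pct`,
#'   `m`, `k`, per-subject SDs and means, and a `relative_defined` flag
#'   (FALSE when any subject mean is zero, in which case the relative
#'   precision is NA).
#' @export
short_term_precision <- function(repeats) {
  x <- as.matrix(repeats)
  if (!is.numeric(x)) fail("repeats must be numeric")
  m <- nrow(x); k <- ncol(x)
  if (m < 1 || k < 2) fail("need >= 1 subject and >= 2 repeats")
  sds <- apply(x, 1, stats::sd)
  means <- rowMeans(x)
  absolute <- sqrt(sum(sds^2) / m)
  rel_ok <- all(means != 0)
  relative <- if (rel_ok) 100 * sqrt(sum((sds / means)^2) / m) else NA_real_
  structure(list(absolute = absolute, relative_pct = relative,
                 relative_defined = rel_ok,
                 m = m, k = k, subject_sd = sds, subject_mean = means),
            class = "precision_result")
}

#' @export
print.precision_result <- function(x, ...) {
  cat(sprintf("short-term precision: %.3g (%.3g%%), %d subjects x %d repeats\n",
              x$absolute, x$relative_pct, x$m, x$k))
  invisible(x)
}
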