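#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed` and
#' restores the previous RNG state afterwards, so that seeded simulator calls
#' do not perturb the caller's random stream.
#'
#' @param seed Integer seed (`NULL` leaves the RNG untouched).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a stream of child seeds from one master seed
#'
#' @param seed Master seed.
#' @param n Number of child seeds.
#' @return Integer vector of `n` seeds, each below 2^31.
#' @keywords internal
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Analytic envelope of a real signal (columns of a matrix) via the FFT
# analytic-signal construction.
envelope_mat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(x) * h
  Mod(stats::mvfft(X, inverse = TRUE) / n)
}

# Hann window of length n (periodic form is irrelevant here; symmetric used).
hann <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
}

fail <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
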