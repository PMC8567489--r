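make_xy <- function(n = 40, p = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  beta <- rep_len(c(1, -0.5, 0.2, 0, 0), p)
  y <- X %*% beta + rnorm(n, 0, 0.3)
  list(X = X, y = as.numeric(y))
}

test_that("a response proportional to one column is fit exactly by 1 component", {
  # centered, sample-orthogonal predictors (orthogonal polynomials), so
  # the first weight vector is exactly the informative axis
  X <- unclass(stats::poly(1:20, 3))
  colnames(X) <- c("a", "b", "c")
  y <- 2.5 * X[, 2]
  fit <- pls_fit(X, y, ncomp = 1, scale = FALSE)
  expect_gt(fit$r_squared, 1 - 1e-10)
})

test_that("full-rank PLS equals the ordinary least-squares solution", {
  d <- make_xy()
  fit <- pls_fit(d$X, d$y, ncomp = 5, scale = FALSE)
  ols <- solve(crossprod(cbind(1, d$X)), crossprod(cbind(1, d$X), d$y))
  expect_lt(max(abs(fit$coefficients - ols[-1])), 1e-8)
  expect_lt(abs(fit$intercept - ols[1]), 1e-8)
})

test_that("successive score vectors are mutually orthogonal", {
  d <- make_xy(p = 6, seed = 3)
  fit <- pls_fit(d$X, d$y, ncomp = 4)
  G <- crossprod(fit$T)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)
})

test_that("coefficients reproduce the training predictions", {
  d <- make_xy(seed = 4)
  fit <- pls_fit(d$X, d$y, ncomp = 3)
  expect_equal(predict(fit, d$X), fit$fitted, tolerance = 1e-10)
})

test_that("zero-variance columns are rejected by name", {
  d <- make_xy()
  d$X[, 3] <- 7
  expect_error(pls_fit(d$X, d$y), "x3")
})

test_that("PLS agrees with an independent implementation", {
  skip_if_not_installed("mixOmics")
  d <- make_xy(n = 30, p = 4, seed = 5)
  fit <- pls_fit(d$X, d$y, ncomp = 2)
  ref <- mixOmics::pls(d$X, d$y, ncomp = 2, scale = TRUE, mode = "regression")
  pred_ref <- predict(ref, d$X)$predict[, 1, 2]
  expect_lt(max(abs(fit$fitted - pred_ref)), 1e-6)
})

test_that("LOOCV produces one out-of-fold prediction per subject", {
  d <- make_xy(n = 25)
  cv <- cross_validated_pls(d$X, d$y, ncomp = 2, scheme = "loocv")
  expect_length(cv$predictions, 25)
  expect_true(all(is.finite(cv$predictions)))
  expect_true(is.finite(cv$rho) && is.finite(cv$rmse))
})

test_that("each LOOCV prediction comes from a model trained without it", {
  set.seed(6)
  n <- 24
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c(1, -1), length.out = n)
  cv <- cross_validated_pls(X, y, ncomp = 2, scheme = "loocv")
  for (i in c(1, 10, 24)) {
    fit <- pls_fit(X[-i, ], y[-i], ncomp = 2)
    manual <- predict(fit, X[i, , drop = FALSE]) - mean(y[-i])
    expect_equal(cv$predictions[i], manual, tolerance = 1e-10)
  }
})

test_that("stratified k-fold keeps both classes in every training set", {
  set.seed(7)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(1, -1), c(20, 10))
  cv <- cross_validated_pls(X, y, ncomp = 2, scheme = "kfold", k = 3,
                            seed = 8)
  for (f in 1:3) {
    expect_equal(length(unique(y[cv$folds != f])), 2)
  }
})

test_that("a single-class fold is a named failure", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(1, -1), c(9, 1))
  expect_error(cross_validated_pls(X, y, scheme = "loocv"),
               "degenerate fold")
})
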