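fg <- seq(4, 9, by = 0.25)
dg <- exp(seq(log(5), log(400), length.out = 64))

test_that("a noiseless lognormal BSC inverts to the right Q90", {
  ker <- build_kernel(fg, dg)
  truth <- new_pore_size_distribution(dg, dlnorm(dg, log(40), 0.3), 12)
  b <- theoretical_bsc(ker, truth)
  inv <- invert_distribution(list(spectrum = data.frame(frequency = fg, bsc = b)),
                             ker, inversion_config(noise_frac = 1e-4))
  q90t <- describe_distribution(truth)$q90
  expect_lt(abs(inv$descriptors$q90 - q90t) / q90t, 0.10)
  # forward -> inverse -> forward residual below the (tiny) noise floor
  b_back <- theoretical_bsc(ker, inv)
  expect_lt(sqrt(mean((b_back - b)^2)) / sqrt(mean(b^2)), 0.02)
})

test_that("a delta BSC inverts to a peak at the right diameter", {
  ker <- build_kernel(fg, dg)
  j <- which.min(abs(dg - 60))
  b <- 5 * ker$K[, j]
  inv <- invert_distribution(list(spectrum = data.frame(frequency = fg, bsc = b)),
                             ker, inversion_config(lambda = 1e-6))
  expect_lte(abs(which.min(abs(dg - inv$descriptors$peak)) - j), 1)
})

test_that("inversion is scale-equivariant", {
  ker <- build_kernel(fg, dg)
  truth <- new_pore_size_distribution(dg, dlnorm(dg, log(35), 0.25), 10)
  b <- theoretical_bsc(ker, truth)
  i1 <- invert_distribution(list(spectrum = data.frame(frequency = fg, bsc = b)),
                            ker, inversion_config(lambda = 1e-4))
  i3 <- invert_distribution(list(spectrum = data.frame(frequency = fg, bsc = 3 * b)),
                            ker, inversion_config(lambda = 1e-4))
  expect_equal(i3$density, i1$density, tolerance = 1e-8)
  expect_equal(i3$areal_density / i1$areal_density, 3, tolerance = 1e-8)
  expect_equal(unlist(i3$descriptors), unlist(i1$descriptors),
               tolerance = 1e-8)
})

test_that("more smoothing never increases the total variation", {
  ker <- build_kernel(fg, dg)
  truth <- new_pore_size_distribution(dg, dlnorm(dg, log(40), 0.3), 12)
  set.seed(41)
  b <- pmax(theoretical_bsc(ker, truth) * (1 + 0.05 * rnorm(length(fg))), 0)
  # over the lambda range the discrepancy principle searches; far beyond
  # it the ridge/normalization interplay can plateau the TV
  tv <- sapply(c(1e-6, 1e-5, 1e-4, 1e-3, 1e-2), function(lam) {
    inv <- invert_distribution(list(spectrum = data.frame(frequency = fg, bsc = b)),
                               ker, inversion_config(lambda = lam))
    sum(abs(diff(inv$density)))
  })
  expect_true(all(diff(tv) <= 1e-9))
})

test_that("degenerate inversion inputs fail cleanly", {
  ker <- build_kernel(fg, dg)
  zero <- list(spectrum = data.frame(frequency = fg, bsc = numeric(length(fg))))
  expect_error(invert_distribution(zero, ker), "no signal")
  few <- list(spectrum = data.frame(frequency = fg[1:5],
                                    bsc = rep(1, 5)))
  expect_error(invert_distribution(few, ker), "grid|signal")
})

test_that("descriptors of a Gaussian density follow the closed forms", {
  d_fine <- seq(10, 70, by = 0.1)
  dist <- new_pore_size_distribution(d_fine, dnorm(d_fine, 40, 5))
  de <- describe_distribution(dist)
  expect_equal(de$peak, 40, tolerance = 0.11)
  expect_equal(de$fwhm, 2.3548 * 5, tolerance = 0.05)
  expect_lt(de$fwhm_min, de$peak); expect_gt(de$fwhm_max, de$peak)
  expect_equal(de$fwhm, de$fwhm_max - de$fwhm_min, tolerance = 1e-12)
})

test_that("lognormal quantile descriptors match the analytic values", {
  d_fine <- exp(seq(log(5), log(400), length.out = 2000))
  dist <- new_pore_size_distribution(d_fine, dlnorm(d_fine, log(40), 0.3))
  de <- describe_distribution(dist)
  expect_equal(de$q10, qlnorm(0.1, log(40), 0.3), tolerance = 0.2)
  expect_equal(de$q90, qlnorm(0.9, log(40), 0.3), tolerance = 0.2)
  expect_lte(de$q10, de$q90)
})

test_that("a flat density has no unique peak", {
  dist <- new_pore_size_distribution(dg, rep(1, 64))
  expect_error(describe_distribution(dist), "no unique peak")
})

test_that("the descriptor set matches the reported parameter family", {
  dist <- new_pore_size_distribution(dg, dlnorm(dg, log(40), 0.3))
  expect_named(describe_distribution(dist),
               c("peak", "q10", "q90", "fwhm", "fwhm_min", "fwhm_max"))
})
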