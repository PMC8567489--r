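test_that("kernel follows the 2-D Rayleigh power laws at small ka", {
  sl <- study_rayleigh_limit()
  expect_lt(abs(sl$slope_frequency - 3) / 3, 0.02)
  expect_lt(abs(sl$slope_diameter - 4) / 4, 0.02)
})

test_that("zero acoustic contrast gives a vanishing kernel", {
  ac <- bone_acoustics(matrix_speed = 1500, matrix_density = 1.0)
  ker <- build_kernel(c(4, 9), c(30, 300), ac)
  expect_true(all(ker$K == 0))
})

test_that("kernel is non-negative and finite over the analysis ranges", {
  ker <- build_kernel(seq(4, 9, 0.5), exp(seq(log(5), log(400), length.out = 32)))
  expect_true(all(is.finite(ker$K)))
  expect_true(all(ker$K >= 0))
})

test_that("ka beyond the truncation validity is refused", {
  expect_error(build_kernel(c(100), c(5000)), "ka")
})

test_that("unsorted grids are rejected", {
  expect_error(build_kernel(c(9, 4), c(30, 300)), "sorted")
})

test_that("theoretical BSC of a delta distribution is the kernel column", {
  dg <- exp(seq(log(10), log(200), length.out = 32))
  ker <- build_kernel(seq(4, 9, 0.5), dg)
  w <- numeric(32); w[17] <- 1
  dist <- new_pore_size_distribution(dg, w, areal_density = 7)
  b <- theoretical_bsc(ker, dist)
  dens <- dist$density[17] * cortbs:::grid_weights(dg)[17]
  expect_equal(b, 7 * ker$K[, 17] * dens, tolerance = 1e-12)
})

test_that("theoretical BSC is linear in the distribution (superposition)", {
  dg <- exp(seq(log(10), log(200), length.out = 32))
  ker <- build_kernel(seq(4, 9, 0.5), dg)
  p1 <- dlnorm(dg, log(30), 0.2)
  p2 <- dlnorm(dg, log(90), 0.2)
  d1 <- new_pore_size_distribution(dg, p1, 10)
  d2 <- new_pore_size_distribution(dg, p2, 10)
  dm <- new_pore_size_distribution(dg, 0.5 * d1$density + 0.5 * d2$density, 10)
  expect_equal(theoretical_bsc(ker, dm),
               0.5 * theoretical_bsc(ker, d1) + 0.5 * theoretical_bsc(ker, d2),
               tolerance = 1e-10)
})

test_that("theoretical BSC matches a brute-force per-pore summation", {
  dg <- exp(seq(log(10), log(200), length.out = 48))
  fg <- seq(4, 9, 0.5)
  ker <- build_kernel(fg, dg)
  set.seed(3)
  d <- pmin(pmax(rlnorm(1e4, log(40), 0.25), dg[1]), dg[length(dg)])
  # brute force: average kernel over individually sampled pores
  idx <- findInterval(d, dg, all.inside = TRUE)
  frac <- (d - dg[idx]) / (dg[idx + 1] - dg[idx])
  brute <- sapply(seq_along(fg), function(i)
    mean(ker$K[i, idx] * (1 - frac) + ker$K[i, idx + 1] * frac)) * 12
  dist <- new_pore_size_distribution(dg, dlnorm(dg, log(40), 0.25), 12)
  b <- theoretical_bsc(ker, dist)
  expect_lt(max(abs(b - brute) / brute), 0.03)
})

test_that("a distribution on a mismatched grid is rejected", {
  dg <- exp(seq(log(10), log(200), length.out = 32))
  ker <- build_kernel(seq(4, 9, 0.5), dg)
  dist <- new_pore_size_distribution(dg * 1.5, rep(1, 32), 1)
  expect_error(theoretical_bsc(ker, dist), "grid")
})
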