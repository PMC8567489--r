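test_that("a pore-free phantom yields exactly one echo per scanline", {
  pop <- empty_population()
  geom <- small_geom()
  rf <- synthesize_rf(pop, geom, snr_db = Inf, seed = 1)
  cw <- pop$acoustics$coupling_speed / 1000
  t_surf <- 2 * geom$standoff / cw
  env <- cortbs:::envelope_mat(rf$samples[, , 1, 1])
  for (q in c(1, 64, 128)) {
    e <- env[, q]
    pk <- which(e > 0.5 * max(e))
    # a single contiguous peak at the surface delay
    expect_lt(max(diff(pk)), 5)
    expect_lt(abs((which.max(e) - 1) / rf$sampling_rate - t_surf), 0.15)
  }
})

test_that("RF synthesis is reproducible under a fixed seed", {
  pop <- sample_pore_population(phantom_mixture(), c(10, 5, 4), seed = 2)
  rf1 <- synthesize_rf(pop, small_geom(), seed = 3)
  rf2 <- synthesize_rf(pop, small_geom(), seed = 3)
  expect_identical(rf1$samples, rf2$samples)
})

test_that("invalid acquisition requests fail early", {
  pop <- empty_population()
  expect_error(synthesize_rf(pop, small_geom(), snr_db = -5), "snr_db")
  expect_error(synthesize_rf(pop, small_geom(center_frequency = 30)),
               "Nyquist")
  expect_error(
    synthesize_rf(empty_population(slab = c(20, 5, 60)), small_geom()),
    "time axis")
})

test_that("log-spectral ratio of two depth windows recovers alpha(f)", {
  # oracle: direct Welch-style spectra on the generated lines at known
  # window positions, bypassing the estimation chain
  mix <- phantom_mixture(density = 12)
  pop <- sample_pore_population(mix, c(40, 5, 5), seed = 11)
  geom <- acquisition_geometry(sweep_tilts = seq(-7, 7, 1),
                               steering_angles = 0)
  rf <- synthesize_rf(pop, geom, alpha0 = 2, alphaf = 0.1, snr_db = 30,
                      seed = 12)
  cw <- pop$acoustics$coupling_speed / 1000
  cb <- pop$acoustics$matrix_speed / 1000
  fs <- rf$sampling_rate
  i_surf <- round(2 * geom$standoff / cw * fs) + 1
  ng <- round(2 * 2 / cb * fs)           # 2-mm windows
  nfft <- 256
  w <- cortbs:::hann(ng)
  spec_at <- function(z) {
    i0 <- i_surf + round(2 * z / cb * fs)
    acc <- 0
    for (it in seq_len(dim(rf$samples)[4])) {
      seg <- rf$samples[i0:(i0 + ng - 1), , 1, it] * w
      acc <- acc + rowMeans(Mod(mvfft(rbind(seg,
        matrix(0, nfft - ng, ncol(seg)))))^2)
    }
    acc
  }
  f <- fs * (0:(nfft / 2)) / nfft
  sel <- which(f >= 5 & f <= 8)
  # two 2-mm windows 2 mm apart, the shallow one clear of the surface echo
  ratio_db <- 10 * log10(spec_at(0.5)[sel] / spec_at(2.5)[sel])
  alpha_hat <- ratio_db / (2 * 2)        # two-way, 2 mm apart
  alpha_true <- 2 + 0.1 * f[sel]
  expect_lt(median(abs(alpha_hat - alpha_true) / alpha_true), 0.05)
})

test_that("the analysis band lies inside the transducer band", {
  geom <- acquisition_geometry()
  expect_lte(geom$center_frequency + 2 * geom$bandwidth_sigma,
             geom$sampling_rate / 2)
  expect_gte(9, geom$center_frequency)
  expect_lte(4, geom$center_frequency)
})
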