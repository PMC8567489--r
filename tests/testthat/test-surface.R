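roi_default <- list(x = c(-15, 15), z = c(2, 9))

surface_run <- function(tilt, sweep = 0) {
  pop <- empty_population(slab = c(40, 5, 4))
  geom <- acquisition_geometry(sweep_tilts = sweep, steering_angles = 0,
                               n_samples = 1024)
  rf <- synthesize_rf(pop, geom, surface_tilt = tilt, snr_db = Inf, seed = 2)
  img <- beamform_compound(rf)
  # keep the lateral range where the tilted plane stays inside the gate
  m <- tan(tilt * pi / 180)
  x_ok <- if (m > 0) c((roi_default$z[1] + 0.5 - 5) / max(m, 1e-9), 15)
          else roi_default$x
  roi <- list(x = c(max(-15, x_ok[1]), min(15, (roi_default$z[2] - 5.5) /
                                             max(m, 1e-9))),
              z = roi_default$z)
  if (m == 0) roi$x <- roi_default$x
  detect_surface(img, roi = roi)
}

test_that("a flat reflector gives near-zero inclination everywhere", {
  surf <- surface_run(0)
  expect_lt(max(abs(surf$map$incl_inplane), na.rm = TRUE), 0.5)
  expect_true(all(surf$map$accept_ref))
})

test_that("an 8-degree plane is recovered and accepted for reference", {
  surf <- surface_run(8)
  med <- median(surf$map$inclination, na.rm = TRUE)
  expect_lt(abs(med - 8), 1)
  expect_gt(mean(surf$map$accept_ref), 0.8)
})

test_that("a 20-degree plane is rejected for reference, kept for backscatter", {
  surf <- surface_run(20)
  med <- median(surf$map$inclination, na.rm = TRUE)
  expect_lt(abs(med - 20), 2)
  expect_equal(sum(surf$map$accept_ref), 0)
  expect_gt(mean(surf$map$accept_bs), 0.8)
})

test_that("raising the surface tilt never gains reference-accepted lines", {
  counts <- sapply(c(0, 6, 12, 20), function(t)
    sum(surface_run(t)$map$accept_ref))
  expect_true(all(diff(counts) <= 0))
})

test_that("reference acceptance is a subset of backscatter acceptance", {
  surf <- cached_rf_chain()$surf
  expect_true(all(!surf$map$accept_ref | surf$map$accept_bs))
  expect_true(all(abs(surf$map$inclination) <= 90, na.rm = TRUE))
})

test_that("an echo-free image fails with 'surface not found'", {
  img <- cached_rf_chain()$img
  dark <- img
  dark$envelope <- array(0, dim = dim(img$envelope))
  expect_error(detect_surface(dark, roi = roi_default), "surface not found")
})
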