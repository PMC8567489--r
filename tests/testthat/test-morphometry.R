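annulus_volume <- function(seed = 1, noise = 0, psf = 0, mix = NULL,
                           slab = c(47.2, 5, 3), n_slices = 4) {
  pop <- if (is.null(mix)) empty_population(slab = slab) else
    sample_pore_population(mix, slab, seed = seed)
  list(pop = pop,
       vol = synthesize_microct(pop, ct_params(noise_sd = noise,
                                               psf_sigma_um = psf,
                                               n_slices = n_slices),
                                seed = seed + 1))
}

test_that("segmentation reproduces the generating annulus", {
  av <- annulus_volume()
  masks <- segment_cortex(av$vol)
  truth <- av$vol$truth$cortex_mask
  expect_true(all(masks$cortical == truth))
  expect_true(all(masks$cortical == (masks$periosteal & !masks$endosteal)))
})

test_that("segmentation stays accurate under PSF blur and noise", {
  av <- annulus_volume(seed = 3, noise = 20, psf = 45,
                       mix = phantom_mixture(d_um = 60, density = 10))
  masks <- segment_cortex(av$vol)
  truth <- av$vol$truth$cortex_mask
  dice <- 2 * sum(masks$cortical & truth) /
    (sum(masks$cortical) + sum(truth))
  expect_gte(dice, 0.95)
})

test_that("an ROI sector is a subset of the cortex", {
  av <- annulus_volume()
  masks <- segment_cortex(av$vol, roi_sector = c(-40, 40))
  expect_true(all(!masks$roi | masks$cortical))
  expect_gt(sum(masks$roi), 0)
  expect_lt(sum(masks$roi), sum(masks$cortical))
  expect_error(segment_cortex(av$vol, roi_sector = c(400, 401)), "ROI")
})

test_that("annulus thickness is recovered to one voxel", {
  av <- annulus_volume()
  th <- cortical_thickness(segment_cortex(av$vol))
  expect_lt(abs(th - 3), av$vol$voxel_um / 1000)
})

test_that("thickness agrees with brute-force boundary doubling", {
  # oracle: per ridge pixel, distance to the nearest background pixel by
  # an explicit scan, doubled and averaged
  av <- annulus_volume()
  masks <- segment_cortex(av$vol)
  m <- masks$cortical
  dt <- EBImage::distmap(m)
  ridge <- which(m & dt >= cortbs:::max3(dt) - 1e-9, arr.ind = TRUE)
  bg <- which(!m, arr.ind = TRUE)
  set.seed(2)
  ridge <- ridge[sample(nrow(ridge), 50), , drop = FALSE]
  brute <- sapply(seq_len(nrow(ridge)), function(i)
    sqrt(min((bg[, 1] - ridge[i, 1])^2 + (bg[, 2] - ridge[i, 2])^2)))
  th_brute <- (2 * mean(brute) - 1) * av$vol$voxel_um / 1000
  th <- cortical_thickness(masks)
  expect_lt(abs(th - th_brute) / th_brute, 0.05)
})

test_that("a pore-free cortex has zero porosity and pore density", {
  av <- annulus_volume()
  masks <- segment_cortex(av$vol)
  seg <- pore_segmentation_bh(av$vol, masks)
  expect_equal(seg$ct_po_bh, 0)
  expect_equal(seg$ct_po_dn, 0)
  dm <- pore_diameter_dist(seg, av$vol$voxel_um)
  expect_length(dm, 0)
  expect_true(isTRUE(attr(dm, "empty")))
})

test_that("resolvable-pore porosity matches the rasterized truth", {
  av <- annulus_volume(seed = 5, mix = phantom_mixture(d_um = 200, density = 1))
  masks <- segment_cortex(av$vol)
  seg <- pore_segmentation_bh(av$vol, masks)
  expect_lt(abs(seg$ct_po_bh - av$vol$truth$porosity), 1)
})

test_that("adding pores never decreases the Burghardt porosity", {
  av0 <- annulus_volume()
  mix <- phantom_mixture(d_um = 200, density = 0.8)
  av1 <- annulus_volume(seed = 7, mix = mix)
  po0 <- pore_segmentation_bh(av0$vol, segment_cortex(av0$vol))$ct_po_bh
  po1 <- pore_segmentation_bh(av1$vol, segment_cortex(av1$vol))$ct_po_bh
  expect_gte(po1, po0)
})

test_that("a matrix-only window maps to zero local porosity", {
  av <- annulus_volume()
  masks <- segment_cortex(av$vol)
  pm <- local_porosity_map(av$vol, masks)
  expect_lt(max(abs(pm$values)), 1e-9)
  expect_error(local_porosity_map(av$vol, masks, window_mm = 50), "window")
})

test_that("single rasterized 200-um pore diameter is recovered to a voxel", {
  pop <- empty_population(slab = c(47.2, 5, 3))
  pop$centers <- matrix(c(23.6, 2.5, 1.5), 1, 3)
  pop$diameters <- 200
  vol <- synthesize_microct(pop, ct_params(noise_sd = 0, psf_sigma_um = 0,
                                           n_slices = 2), seed = 1)
  masks <- segment_cortex(vol)
  seg <- pore_segmentation_bh(vol, masks)
  dm <- pore_diameter_dist(seg, vol$voxel_um)
  expect_length(dm, 1)
  expect_lt(abs(dm - 200), vol$voxel_um)
})

test_that("moment statistics match a direct formula evaluation", {
  x <- c(3.1, 4.7, 2.2, 5.9, 4.4, 3.8, 6.1, 2.9, 5.2, 4.0,
         3.3, 4.9, 5.5, 2.6, 4.1, 3.7, 5.0, 4.3, 3.5, 4.6)
  ms <- moment_stats(x)
  m <- sum(x) / 20
  m2 <- sum((x - m)^2) / 20
  expect_equal(ms$mean, m)
  expect_equal(ms$var, sum((x - m)^2) / 19)
  expect_equal(ms$sd, sqrt(sum((x - m)^2) / 19))
  expect_equal(ms$skewness, (sum((x - m)^3) / 20) / m2^1.5)
  expect_equal(ms$kurtosis, (sum((x - m)^4) / 20) / m2^2)
  expect_equal(ms$q10, as.numeric(quantile(x, 0.1)))
  expect_equal(ms$q90, as.numeric(quantile(x, 0.9)))
})

test_that("moment conventions: Gaussian kurtosis 3, Pearson inequality", {
  set.seed(8)
  g <- rnorm(2e5)
  ms <- moment_stats(g)
  expect_lt(abs(ms$skewness), 0.02)
  expect_lt(abs(ms$kurtosis - 3), 0.05)
  for (i in 1:10) {
    x <- rlnorm(50, 0, runif(1, 0.2, 1))
    s <- moment_stats(x)
    expect_gte(s$kurtosis, 1 + s$skewness^2)
  }
  expect_error(moment_stats(1:5), "too few")
})

test_that("full-section statistics equal ROI statistics for a full sector", {
  av <- annulus_volume(seed = 9, mix = phantom_mixture(d_um = 150, density = 2))
  masks_full <- segment_cortex(av$vol)
  masks_roi <- segment_cortex(av$vol, roi_sector = c(-180, 180))
  expect_true(all(masks_roi$roi == masks_full$cortical))
  seg_f <- pore_segmentation_bh(av$vol, masks_full)
  seg_r <- pore_segmentation_bh(av$vol, masks_roi, roi = TRUE)
  expect_equal(seg_r$ct_po_bh, seg_f$ct_po_bh)
  expect_equal(seg_r$ct_po_dn, seg_f$ct_po_dn)
})

test_that("finer voxels detect a strictly larger fraction of true pores", {
  mix <- phantom_mixture(d_um = 95, density = 6)
  pop <- sample_pore_population(mix, c(47.2, 5, 3), seed = 21)
  frac_detected <- function(voxel_um) {
    vol <- synthesize_microct(pop, ct_params(voxel_um = voxel_um,
                                             noise_sd = 0, psf_sigma_um = 0,
                                             n_slices = 1), seed = 22)
    seg <- pore_segmentation_bh(vol, segment_cortex(vol))
    seg$n_pores / length(pop$diameters)
  }
  expect_gt(frac_detected(30), frac_detected(60.7))
})
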