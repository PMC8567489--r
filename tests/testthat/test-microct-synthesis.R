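test_that("a pore-free noiseless volume is uniform matrix vBMD in the cortex", {
  pop <- empty_population(slab = c(47.2, 5, 3))
  vol <- synthesize_microct(pop, ct_params(noise_sd = 0, psf_sigma_um = 0,
                                           n_slices = 2), seed = 1)
  cortex_vals <- vol$data[, , 1][vol$truth$cortex_mask]
  expect_true(all(cortex_vals == pop$acoustics$matrix_vbmd))
  expect_true(all(vol$data[, , 1][!vol$truth$cortex_mask] == 0))
})

test_that("pore-voxel fraction matches the analytic areal porosity", {
  mix <- phantom_mixture(d_um = 120, density = 4)
  pop <- sample_pore_population(mix, c(47.2, 5, 3), seed = 2)
  vol <- synthesize_microct(pop, ct_params(noise_sd = 0, psf_sigma_um = 0,
                                           n_slices = 2), seed = 3)
  expect_lt(abs(vol$truth$porosity - areal_porosity(pop)) /
              areal_porosity(pop), 0.01)
})

test_that("30-um pores are sub-voxel while 200-um pores span >3 voxels", {
  ac <- bone_acoustics()
  base <- empty_population(slab = c(47.2, 5, 3), acoustics = ac)
  mk <- function(d) {
    p <- base
    p$centers <- matrix(c(23.6, 2.5, 1.5), 1, 3)
    p$diameters <- d
    synthesize_microct(p, ct_params(noise_sd = 0, psf_sigma_um = 0,
                                    n_slices = 1), seed = 1)
  }
  v30 <- mk(30)
  thr <- 0.5 * ac$matrix_vbmd
  # unresolved: no voxel drops below the pore threshold, but partial
  # volume still lowers some voxel values
  expect_equal(sum(v30$data[, , 1][v30$truth$cortex_mask] < thr), 0)
  expect_gt(sum(v30$data[, , 1][v30$truth$cortex_mask] <
                  0.99 * ac$matrix_vbmd), 0)
  v200 <- mk(200)
  expect_gt(sum(v200$data[, , 1][v200$truth$cortex_mask] < thr), 3)
})

test_that("volumes are reproducible and invalid sizes fail", {
  pop <- empty_population(slab = c(10, 5, 2))
  p <- ct_params(n_slices = 2)
  v1 <- synthesize_microct(pop, p, seed = 9)
  v2 <- synthesize_microct(pop, p, seed = 9)
  expect_identical(v1$data, v2$data)
  tiny <- empty_population(slab = c(0.01, 5, 0.01))
  expect_error(synthesize_microct(tiny, ct_params()), "voxel")
})
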