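# Shared fixtures. RF simulations in unit tests use a trimmed acquisition
# (few sweep tilts, one steering angle) so the suite stays fast; the
# acceptance tests exercise the full default geometry.

small_geom <- function(...) {
  acquisition_geometry(sweep_tilts = seq(-2, 2, by = 2),
                       steering_angles = 0, ...)
}

# monodisperse reference phantom used by controlled recovery checks
phantom_mixture <- function(d_um = 30, density = 12) {
  diameter_mixture(baseline_log_mean = log(d_um), baseline_log_sd = 0.02,
                   tail_weight = 0, pore_density = density, hard_core = 60)
}

# a pore population with no pores (surface-only phantom)
empty_population <- function(slab = c(20, 5, 4), acoustics = bone_acoustics()) {
  structure(list(centers = matrix(numeric(0), 0, 3),
                 diameters = numeric(0), slab_extent = slab,
                 pore_axis = c(0, 1, 0),
                 params = diameter_mixture(), acoustics = acoustics),
            class = "pore_population")
}

# one cached mid-size RF run shared by the spectral-processing tests
cached_rf_chain <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      mix <- phantom_mixture()
      pop <- sample_pore_population(mix, slab_extent = c(40, 5, 4), seed = 71)
      geom <- acquisition_geometry(sweep_tilts = seq(-7, 7, by = 2),
                                   steering_angles = 0)
      rf <- synthesize_rf(pop, geom, alpha0 = 2, alphaf = 0.1,
                          snr_db = 30, seed = 72)
      img <- beamform_compound(rf)
      surf <- detect_surface(img, roi = list(x = c(-18, 18), z = c(3, 8)))
      nds <- compute_nds(rf, surf)
      cache <<- list(pop = pop, geom = geom, rf = rf, img = img,
                     surf = surf, nds = nds)
    }
    cache
  }
})
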