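#' Synthesize pulse-echo RF backscatter data from a pore population
#'
#' Forward model for the compound volume scan. Each A-line is the sum of
#' (i) a specular surface echo with the planar reflection coefficient of the
#' coupling/bone impedance contrast, attenuated by an obliquity factor when
#' the beam is inclined to the surface normal, and (ii) one echo per
#' insonified pore with amplitude proportional to the square root of the
#' cylinder backscatter cross-section \eqn{\sqrt{\sigma_b(f, d)}}, a uniform
#' random phase, the two-way propagation delay, and two-way amplitude decay
#' \eqn{10^{-\alpha(f)\, 2\zeta/20}} with \eqn{\alpha(f) = \alpha_0 +
#' \alpha_f f} (dB/mm one-way) at depth \eqn{\zeta} below the surface.
#' White Gaussian noise is added at the configured SNR (relative to the RMS
#' of the pore backscatter signal).
#'
#' Pores insonified by a scanline are those whose lateral distance from the
#' (possibly steered) beam axis is within half the effective beam width.
#' Refraction at the bone surface is neglected. The out-of-plane sweep tilt
#' lengthens propagation paths by `1/cos(tilt)` and adds to the beam/surface
#' inclination; echo phases are drawn independently per (tilt, steering,
#' scanline) so that frames carry independent speckle, emulating the axial
#' decorrelation of real pore networks.
#'
#' @param pop A [sample_pore_population()] object (may contain zero pores).
#' @param geom An [acquisition_geometry()].
#' @param alpha0,alphaf Programmed attenuation intercept (dB/mm) and slope
#'   (dB/MHz/mm) of the cortical matrix.
#' @param surface_tilt In-plane inclination of the planar bone surface
#'   (degrees); the surface is `z0(x) = standoff + tan(tilt) * x`.
#' @param snr_db Signal-to-noise ratio in dB (must be non-negative; `Inf`
#'   disables noise).
#' @param tilt_decorrelate If `TRUE` (default), every sweep tilt insonifies
#'   a fresh pore realization drawn from the population's mixture
#'   parameters, emulating the decorrelation of the pore network along the
#'   bone axis as the imaging plane sweeps; if `FALSE`, all tilts see the
#'   one supplied cross-section.
#' @param seed Integer seed (phases, per-tilt realizations, noise).
#' @return Object of class `rf_dataset`: `samples` is a 4-D array
#'   (time x scanline x steering x tilt), plus the time axis (us), geometry,
#'   acoustics, and a `truth` record of the programmed ground truth.
#' @export
synthesize_rf <- function(pop, geom = acquisition_geometry(),
                          alpha0 = 2.0, alphaf = 0.10,
                          surface_tilt = 0, snr_db = 30,
                          tilt_decorrelate = TRUE, seed = NULL) {
  stopifnot(inherits(pop, "pore_population"),
            inherits(geom, "acquisition_geometry"))
  if (snr_db < 0) fail("snr_db must be non-negative (got %g)", snr_db)
  ac <- pop$acoustics
  fs <- geom$sampling_rate
  nt <- geom$n_samples
  f_ny <- fs / 2
  if (geom$center_frequency + 2 * geom$bandwidth_sigma > f_ny)
    fail("usable band (%g + 2*%g MHz) exceeds Nyquist (%g MHz)",
         geom$center_frequency, geom$bandwidth_sigma, f_ny)
  cw <- ac$coupling_speed / 1000   # mm/us
  cb <- ac$matrix_speed / 1000
  xl <- scanline_positions(geom)
  m <- tan(surface_tilt * pi / 180)
  surf_fun <- function(x) geom$standoff + m * x
  t_max <- 2 * (max(surf_fun(xl)) / cw + pop$slab_extent[3] / cb) + 2
  if (t_max > nt / fs)
    fail("time axis (%d samples at %g MHz) too short to cover surface + %g mm of bone",
         nt, fs, pop$slab_extent[3])

  nf <- nt %/% 2 + 1
  f_full <- (0:(nf - 1)) * fs / nt            # MHz
  pulse_full <- exp(-(f_full - geom$center_frequency)^2 /
                      (2 * geom$bandwidth_sigma^2))
  # spectra are only computed on the pulse support (everything else is
  # numerically zero); bsel indexes the support within the one-sided grid
  bsel <- which(pulse_full > 3e-3)
  f <- f_full[bsel]
  pulse <- pulse_full[bsel]
  npore <- length(pop$diameters)
  R <- reflection_coefficient(ac)

  # pore echo amplitude spectra: interpolate sqrt(sigma_b) on a diameter grid
  if (npore > 0) {
    d_lo <- min(pop$diameters, qmixture(1e-6, pop$params)) * 0.9
    d_hi <- max(pop$diameters, qmixture(1 - 1e-7, pop$params)) * 1.1
    dg <- exp(seq(log(max(d_lo, 1)), log(d_hi), length.out = 48))
    fk <- pmax(f, 1e-3)
    ker <- build_kernel(fk, dg, ac)
    amp_grid <- sqrt(ker$K)                   # nf x ndg
  }

  tilts <- geom$sweep_tilts
  steers <- geom$steering_angles
  samples <- array(0, dim = c(nt, geom$n_elements, length(steers), length(tilts)))
  sig_ss <- 0; sig_n <- 0

  with_seed(seed, {
    for (it in seq_along(tilts)) {
      path_fac <- 1 / cos(tilts[it] * pi / 180)
      if (npore > 0) {
        pop_t <- if (tilt_decorrelate && it > 1)
          sample_pore_population(pop$params, pop$slab_extent, seed = NULL,
                                 acoustics = ac)
        else pop
        d_t <- pmin(pmax(pop_t$diameters, dg[1]), dg[length(dg)])
        d_idx <- findInterval(d_t, dg, all.inside = TRUE)
        d_frac <- (d_t - dg[d_idx]) / (dg[d_idx + 1] - dg[d_idx])
        px <- pop_t$centers[, 1] - pop_t$slab_extent[1] / 2  # centered laterally
        pz <- pop_t$centers[, 3]                             # depth below surface
        npore_t <- length(d_t)
      } else npore_t <- 0L
      for (is in seq_along(steers)) {
        th <- steers[is] * pi / 180
        tanth <- tan(th); costh <- cos(th)
        # surface crossing depth per line (planar surface, straight ray)
        zs <- (geom$standoff + m * xl) / (1 - m * tanth)
        t_surf <- 2 * zs / costh * path_fac / cw
        incl <- sqrt((steers[is] - surface_tilt)^2 + tilts[it]^2)
        a_surf <- R * exp(-(incl / specular_sigma_deg)^2)
        S <- matrix(0i, length(bsel), geom$n_elements)
        # surface echoes (all lines)
        S <- S + pulse * (a_surf * exp(-2i * pi * outer(f, t_surf)))
        if (npore_t > 0) {
          # pore-line pairing: global surface depth at pore lateral position
          zg <- surf_fun(px) + pz               # global pore depth
          ax_lo <- px - zg * tanth - geom$beamwidth / 2
          ax_hi <- px - zg * tanth + geom$beamwidth / 2
          il_lo <- pmax(1L, ceiling((ax_lo - xl[1]) / geom$pitch) + 1L)
          il_hi <- pmin(geom$n_elements, floor((ax_hi - xl[1]) / geom$pitch) + 1L)
          keep <- which(il_hi >= il_lo)
          if (length(keep)) {
            counts <- il_hi[keep] - il_lo[keep] + 1L
            pj <- rep(keep, counts)
            lj <- unlist(lapply(seq_along(keep), function(q)
              il_lo[keep[q]]:il_hi[keep[q]]), use.names = FALSE)
            zsj <- zs[lj]
            zeta <- pmax(0, (zg[pj] - zsj) / costh)   # bone path (one-way)
            tj <- (2 * zsj / costh / cw + 2 * zeta / cb) * path_fac
            phi <- stats::runif(length(pj), 0, 2 * pi)
            # spectra [support bins x pairs]: amplitude-interpolated
            # cross-sections with the two-way attenuation decay and the
            # delay/phase rotation applied in the compiled accumulator
            nb <- length(bsel)
            A <- amp_grid[, d_idx[pj]] * (1 - rep(d_frac[pj], each = nb)) +
                 amp_grid[, d_idx[pj] + 1L] * rep(d_frac[pj], each = nb)
            cdec <- -log(10) / 20 * 2
            S <- S + .accum_spectra(A, cdec * (alpha0 + alphaf * f[1]),
                                    cdec * alphaf * (f[2] - f[1]),
                                    f[1], f[2] - f[1], pulse,
                                    zeta, phi, tj,
                                    as.integer(lj), geom$n_elements)
          }
        }
        # back to time domain (hermitian-symmetric inverse FFT)
        X <- matrix(0i, nt, geom$n_elements)
        X[bsel, ] <- S
        if (nt %% 2 == 0 && nf %in% bsel) X[nf, ] <- Re(X[nf, ])
        mir <- bsel[bsel > 1 & bsel < nf]
        X[nt + 2 - mir, ] <- Conj(X[mir, ])
        x_td <- Re(stats::mvfft(X, inverse = TRUE)) / nt
        samples[, , is, it] <- x_td
      }
    }
    # additive white noise at configured SNR re. backscatter RMS
    if (is.finite(snr_db) && npore > 0) {
      gate0 <- round((2 * geom$standoff / cw + 0.5) * fs)
      gate1 <- min(nt, round((2 * geom$standoff / cw +
                              2 * pop$slab_extent[3] / cb) * fs))
      seg <- samples[gate0:gate1, , , , drop = FALSE]
      rms <- sqrt(mean(seg^2))
      sd_n <- rms * 10^(-snr_db / 20)
      samples <- samples + array(stats::rnorm(length(samples), 0, sd_n),
                                 dim = dim(samples))
    }
    time_us <- (0:(nt - 1)) / fs
    structure(list(samples = samples, time_us = time_us,
                   sampling_rate = fs, geometry = geom, acoustics = ac,
                   truth = list(population = pop, alpha0 = alpha0,
                                alphaf = alphaf, surface_tilt = surface_tilt,
                                standoff = geom$standoff, snr_db = snr_db)),
              class = "rf_dataset")
  })
}
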