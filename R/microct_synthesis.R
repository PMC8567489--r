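#' Micro-CT synthesis parameters
#'
#' @param voxel_um Isotropic voxel size (um), default 60.7 (second-
#'   generation HR-pQCT).
#' @param n_slices Number of cross-sectional slices.
#' @param psf_sigma_um Gaussian in-plane point-spread-function width (um);
#'   0 disables blurring.
#' @param noise_sd Additive Gaussian noise SD (mg HA/cm^3).
#' @param outer_radius Periosteal radius of the cortical annulus (mm).
#' @param supersample In-plane antialiasing factor for the pore raster
#'   (area-coverage partial-volume model).
#' @return List of class `ct_params`.
#' @export
ct_params <- function(voxel_um = 60.7, n_slices = 24, psf_sigma_um = 45,
                      noise_sd = 20, outer_radius = 9, supersample = 4) {
  if (voxel_um <= 0) fail("voxel size must be positive")
  if (psf_sigma_um < 0) fail("PSF width must be >= 0")
  structure(list(voxel_um = voxel_um, n_slices = as.integer(n_slices),
                 psf_sigma_um = psf_sigma_um, noise_sd = noise_sd,
                 outer_radius = outer_radius,
                 supersample = as.integer(supersample)),
            class = "ct_params")
}

#' Synthesize an HR-pQCT-like volume from a pore population
#'
#' The pore slab is wrapped onto a cortical annulus sector: the slab's
#' lateral coordinate becomes arc length along the mid-cortical circle and
#' its depth coordinate becomes radial depth below the periosteal surface.
#' Pores (straight cylinders along the bone axis) are rasterized with an
#' area-coverage partial-volume model, so sub-voxel pores lower the voxel
#' vBMD proportionally to their covered area instead of vanishing. Voxel
#' values are matrix vBMD inside the mineralized matrix and ~0 in pores,
#' the marrow cavity, and the background. A Gaussian in-plane PSF blur and
#' additive Gaussian noise follow.
#'
#' @param pop A [sample_pore_population()] object. The slab's x extent sets
#'   the sector's angular width (a full annulus results when it reaches the
#'   mid-cortical circumference); the z extent sets cortical thickness.
#' @param params A [ct_params()].
#' @param seed Integer seed (noise).
#' @return Object of class `microct_volume`: `data` array (nx x ny x
#'   n_slices, mg HA/cm^3), `voxel_um`, `calibration` (matrix vBMD), and a
#'   `truth` record (coverage volume, pore table in volume coordinates,
#'   masks).
#' @export
synthesize_microct <- function(pop, params = ct_params(), seed = NULL) {
  stopifnot(inherits(pop, "pore_population"), inherits(params, "ct_params"))
  vox <- params$voxel_um / 1000              # mm
  if (any(pop$slab_extent[c(1, 3)] < vox))
    fail("slab smaller than one voxel")
  matrix_vbmd <- pop$acoustics$matrix_vbmd
  ro <- params$outer_radius
  th_c <- pop$slab_extent[3]                 # cortical thickness
  ri <- ro - th_c
  if (ri <= 0.5) fail("outer radius too small for the cortical thickness")
  r_mid <- (ro + ri) / 2
  ang_w <- min(2 * pi, pop$slab_extent[1] / r_mid)
  full <- ang_w >= 2 * pi - 1e-9
  half_w <- ro + 2 * vox
  n <- 2 * ceiling(half_w / vox) + 1
  cx <- (n + 1) / 2
  ax <- (seq_len(n) - cx) * vox              # pixel center coords (mm)
  X <- matrix(ax, n, n)
  Y <- matrix(ax, n, n, byrow = TRUE)
  Rg <- sqrt(X^2 + Y^2)
  Ag <- atan2(Y, X)
  in_ann <- Rg <= ro & Rg >= ri
  in_sec <- if (full) rep(TRUE, length(Ag)) else
    abs(Ag) <= ang_w / 2                    # sector centered on +x axis
  cortex <- in_ann & in_sec
  # pore centers in volume coordinates
  ang_p <- (pop$centers[, 1] / r_mid) - ang_w / 2   # arc length -> angle
  r_p <- ro - pop$centers[, 3]
  pxv <- r_p * cos(ang_p)
  pyv <- r_p * sin(ang_p)
  rad <- pop$diameters / 2000                # mm
  # area-coverage rasterization (supersampled within affected pixels)
  coverage <- matrix(0, n, n)
  ss <- params$supersample
  off <- (seq_len(ss) - (ss + 1) / 2) / ss * vox
  for (j in seq_along(rad)) {
    i0 <- max(1L, 1L + floor((pxv[j] - rad[j] - ax[1]) / vox) - 1L)
    i1 <- min(n, 1L + ceiling((pxv[j] + rad[j] - ax[1]) / vox) + 1L)
    k0 <- max(1L, 1L + floor((pyv[j] - rad[j] - ax[1]) / vox) - 1L)
    k1 <- min(n, 1L + ceiling((pyv[j] + rad[j] - ax[1]) / vox) + 1L)
    if (i1 < i0 || k1 < k0) next
    xs <- ax[i0:i1]; ys <- ax[k0:k1]
    sub <- matrix(0, length(xs), length(ys))
    for (ox in off) for (oy in off) {
      sub <- sub + (outer((xs + ox - pxv[j])^2,
                          (ys + oy - pyv[j])^2, `+`) <= rad[j]^2)
    }
    coverage[i0:i1, k0:k1] <- pmin(1, coverage[i0:i1, k0:k1] + sub / ss^2)
  }
  coverage[!cortex] <- 0
  slice <- matrix(0, n, n)
  slice[cortex] <- matrix_vbmd * (1 - coverage[cortex])
  with_seed(seed, {
    vol <- array(0, dim = c(n, n, params$n_slices))
    psf_px <- params$psf_sigma_um / params$voxel_um
    blurred <- if (psf_px > 0) gauss_blur2d(slice, psf_px) else slice
    for (s in seq_len(params$n_slices)) {
      sl <- blurred
      if (params$noise_sd > 0)
        sl <- sl + matrix(stats::rnorm(n * n, 0, params$noise_sd), n, n)
      vol[, , s] <- sl
    }
    structure(list(
      data = vol, voxel_um = params$voxel_um,
      calibration = list(matrix_vbmd = matrix_vbmd),
      params = params,
      truth = list(coverage = coverage, cortex_mask = cortex,
                   pore_x = pxv, pore_y = pyv, diameters = pop$diameters,
                   porosity = 100 * sum(coverage[cortex]) / sum(cortex),
                   outer_radius = ro, inner_radius = ri,
                   angular_width = ang_w, full_annulus = full,
                   population = pop)),
      class = "microct_volume")
  })
}

# separable Gaussian blur with reflective edges
gauss_blur2d <- function(img, sigma_px) {
  k <- ceiling(3 * sigma_px)
  g <- stats::dnorm(-k:k, sd = sigma_px)
  g <- g / sum(g)
  pad <- function(m, k) {
    rbind(m[k:1, , drop = FALSE], m, m[nrow(m):(nrow(m) - k + 1), , drop = FALSE])
  }
  conv_cols <- function(m) {
    mp <- pad(m, k)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(g))
      out <- out + g[i] * mp[i:(i + nrow(m) - 1), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(img))))
}
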