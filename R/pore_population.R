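#' Acoustic and densitometric material properties
#'
#' Conventional values for mineralized cortical bone matrix and for the
#' fluid/soft-tissue filling of intracortical pores. All values are
#' configurable; none are measured quantities of a specific cohort.
#'
#' @param matrix_speed Longitudinal sound speed in the matrix (m/s).
#' @param matrix_density Matrix mass density (g/cm^3).
#' @param matrix_vbmd Matrix volumetric BMD (mg HA/cm^3).
#' @param fluid_speed Sound speed in the pore fluid (m/s).
#' @param fluid_density Pore-fluid mass density (g/cm^3).
#' @param coupling_speed Sound speed in the soft-tissue/coupling standoff (m/s).
#' @param coupling_density Density of the standoff medium (g/cm^3).
#' @return Object of class `bone_acoustics`.
#' @export
bone_acoustics <- function(matrix_speed = 3800, matrix_density = 1.9,
                           matrix_vbmd = 1100,
                           fluid_speed = 1500, fluid_density = 1.0,
                           coupling_speed = 1540, coupling_density = 1.0) {
  stopifnot(matrix_speed > 0, matrix_density > 0, fluid_speed > 0,
            fluid_density > 0, matrix_vbmd > 0, coupling_speed > 0)
  structure(list(matrix_speed = matrix_speed, matrix_density = matrix_density,
                 matrix_vbmd = matrix_vbmd,
                 fluid_speed = fluid_speed, fluid_density = fluid_density,
                 coupling_speed = coupling_speed,
                 coupling_density = coupling_density),
            class = "bone_acoustics")
}

#' Planar reflection coefficient of the coupling/bone interface
#'
#' Amplitude reflection coefficient for normal incidence from the acoustic
#' impedance contrast between the coupling medium and the bone matrix.
#'
#' @param acoustics A [bone_acoustics()] object.
#' @return Scalar in `(-1, 1)`.
#' @export
reflection_coefficient <- function(acoustics) {
  z_bone <- acoustics$matrix_speed * acoustics$matrix_density
  z_soft <- acoustics$coupling_speed * acoustics$coupling_density
  (z_bone - z_soft) / (z_bone + z_soft)
}

#' Sample a hard-core pore population in a cortical slab
#'
#' Draws pore diameters from the configured lognormal mixture and places the
#' pore centers in the slab cross-section by dart throwing with hard-core
#' rejection. Pores are straight circular cylinders along the bone long axis
#' (the slab y-axis), so placement happens in the (x, z) cross-section.
#'
#' @param params A [diameter_mixture()] object (diameters in um, density in
#'   pores/mm^2, hard-core spacing in um).
#' @param slab_extent Numeric length-3 vector `(x, y, z)` of slab edge
#'   lengths in mm: x lateral (imaging plane), y along the bone axis,
#'   z radial depth.
#' @param seed Integer seed; fixed seed gives a bit-identical population.
#' @param acoustics A [bone_acoustics()] object stored with the population.
#' @param max_attempts Dart-throwing rejection cap per pore.
#' @return Object of class `pore_population` with fields `centers` (n x 3,
#'   mm), `diameters` (um), `slab_extent`, `pore_axis`, `params`,
#'   `acoustics`.
#' @export
sample_pore_population <- function(params, slab_extent = c(20, 5, 4),
                                   seed = NULL,
                                   acoustics = bone_acoustics(),
                                   max_attempts = 1e4) {
  stopifnot(inherits(params, "diameter_mixture"))
  if (any(slab_extent <= 0)) fail("slab_extent must be positive")
  area <- slab_extent[1] * slab_extent[3]
  n <- round(params$pore_density * area)
  hc_mm <- params$hard_core / 1000
  # mean nearest-neighbour distance of a Poisson process: 0.5 / sqrt(density)
  if (hc_mm >= 0.5 / sqrt(params$pore_density))
    fail("hard-core spacing %g um exceeds the mean nearest-neighbour distance %g um implied by the density",
         params$hard_core, 500 / sqrt(params$pore_density))
  with_seed(seed, {
    d <- rmixture(n, params)
    cx <- numeric(n); cz <- numeric(n)
    # grid-accelerated dart throwing
    cell <- max(hc_mm, 1e-3)
    nx_cell <- max(1L, ceiling(slab_extent[1] / cell))
    nz_cell <- max(1L, ceiling(slab_extent[3] / cell))
    grid <- vector("list", nx_cell * nz_cell)
    placed <- 0L
    for (i in seq_len(n)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        px <- stats::runif(1, 0, slab_extent[1])
        pz <- stats::runif(1, 0, slab_extent[3])
        gx <- min(nx_cell, 1L + floor(px / cell))
        gz <- min(nz_cell, 1L + floor(pz / cell))
        clash <- FALSE
        if (hc_mm > 0) {
          for (dxc in -1:1) for (dzc in -1:1) {
            ggx <- gx + dxc; ggz <- gz + dzc
            if (ggx < 1 || ggx > nx_cell || ggz < 1 || ggz > nz_cell) next
            idxs <- grid[[(ggz - 1L) * nx_cell + ggx]]
            if (length(idxs) &&
                any((cx[idxs] - px)^2 + (cz[idxs] - pz)^2 < hc_mm^2)) {
              clash <- TRUE; break
            }
          }
        }
        if (!clash) {
          cx[i] <- px; cz[i] <- pz
          grid[[(gz - 1L) * nx_cell + gx]] <- c(grid[[(gz - 1L) * nx_cell + gx]], i)
          placed <- placed + 1L
          ok <- TRUE
          break
        }
      }
      if (!ok)
        fail("hard-core constraint unsatisfiable after %d attempts; achieved density %.2f of requested %.2f pores/mm^2",
             max_attempts, (placed) / area, params$pore_density)
    }
    centers <- cbind(x = cx, y = rep(slab_extent[2] / 2, n), z = cz)
    structure(list(centers = centers, diameters = d,
                   slab_extent = slab_extent,
                   pore_axis = c(0, 1, 0),
                   params = params, acoustics = acoustics),
              class = "pore_population")
  })
}

#' Analytic areal porosity of a pore population
#'
#' Total pore cross-sectional area over slab cross-sectional area, in
#' percent. Pores are cylinders, so this is also the volume porosity.
#'
#' @param pop A [sample_pore_population()] result.
#' @return Porosity in percent.
#' @export
areal_porosity <- function(pop) {
  stopifnot(inherits(pop, "pore_population"))
  d_mm <- pop$diameters / 1000
  100 * sum(pi * d_mm^2 / 4) / (pop$slab_extent[1] * pop$slab_extent[3])
}

#' @export
print.pore_population <- function(x, ...) {
  cat(sprintf("pore_population: %d pores in %.1f x %.1f x %.1f mm slab\n",
              length(x$diameters), x$slab_extent[1], x$slab_extent[2],
              x$slab_extent[3]))
  cat(sprintf("  diameter median %.1f um, areal porosity %.2f%%\n",
              stats::median(x$diameters), areal_porosity(x)))
  invisible(x)
}
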