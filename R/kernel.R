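#' Backscatter kernel for fluid cylinders in a fluid host
#'
#' Differential backscattering cross-section per unit cylinder length for a
#' fluid cylinder (the pore, filled with marrow/fluid) embedded in a fluid
#' host with the acoustic properties of the mineralized matrix (matrix shear
#' stiffness is neglected). The field is expanded in cylindrical harmonics;
#' continuity of pressure and normal particle velocity at the pore wall
#' determines the modal coefficients
#' \deqn{b_n = -\frac{J_n'(x_0) - \beta_n J_n(x_0)}{H_n'(x_0) - \beta_n H_n(x_0)},
#'   \quad \beta_n = \frac{Z_0}{Z_1}\frac{J_n'(x_1)}{J_n(x_1)},}
#' with \eqn{x_0 = k_0 a}, \eqn{x_1 = k_1 a} the host/pore wavenumber-radius
#' products and \eqn{Z} the acoustic impedances. The backscatter (180 deg)
#' cross-section per unit length is
#' \deqn{\sigma_b = \frac{2}{\pi k_0}\Big|\sum_n \epsilon_n (-1)^n b_n\Big|^2}
#' (units mm, i.e. mm^2 per mm length per unit angle). In the long-wavelength
#' limit this follows the two-dimensional Rayleigh law
#' \eqn{\sigma_b \propto k^3 a^4}.
#'
#' The series is truncated at `N = max(10, ceil(ka) + 4)` terms, which is
#' accurate for `ka` up to a few tens; larger `ka` is refused.
#'
#' @param f_grid Frequency grid (MHz), sorted increasing.
#' @param d_grid Diameter grid (um), sorted increasing.
#' @param acoustics A [bone_acoustics()] object.
#' @return Object of class `bsc_kernel`: list with matrix `K`
#'   (`length(f_grid)` x `length(d_grid)`, cross-section in mm), the grids,
#'   and the acoustic contrast used.
#' @export
build_kernel <- function(f_grid, d_grid, acoustics = bone_acoustics()) {
  stopifnot(all(f_grid > 0), all(d_grid > 0))
  if (is.unsorted(f_grid) || is.unsorted(d_grid))
    fail("frequency and diameter grids must be sorted increasing")
  c0 <- acoustics$matrix_speed      # host = matrix
  c1 <- acoustics$fluid_speed       # scatterer = pore fluid
  z0 <- c0 * acoustics$matrix_density
  z1 <- c1 * acoustics$fluid_density
  a_mm <- d_grid / 2000                       # radius in mm
  k0 <- 2 * pi * f_grid * 1e6 / c0 / 1000     # 1/mm
  k1 <- 2 * pi * f_grid * 1e6 / c1 / 1000
  ka_max <- max(outer(k0, a_mm))
  if (ka_max > 60)
    fail("ka = %.1f beyond modal-series truncation validity (max f = %g MHz, max d = %g um)",
         ka_max, max(f_grid), max(d_grid))
  K <- matrix(0, length(f_grid), length(d_grid),
              dimnames = list(frequency = NULL, diameter = NULL))
  zero_contrast <- abs(z0 - z1) < 1e-12 * z0 && abs(c0 - c1) < 1e-12 * c0
  if (!zero_contrast) {
    for (j in seq_along(a_mm)) {
      x0 <- k0 * a_mm[j]
      x1 <- k1 * a_mm[j]
      nmax <- max(10, ceiling(max(x0, x1)) + 4)
      s <- complex(length.out = length(f_grid))
      for (n in 0:nmax) {
        jn0 <- besselJ(x0, n); yn0 <- besselY(x0, n)
        jn1 <- besselJ(x1, n)
        # derivatives w.r.t. the argument via recurrences
        djn0 <- dbessel(x0, n, besselJ)
        dyn0 <- dbessel(x0, n, besselY)
        djn1 <- dbessel(x1, n, besselJ)
        hn0 <- complex(real = jn0, imaginary = yn0)
        dhn0 <- complex(real = djn0, imaginary = dyn0)
        beta <- (z0 / z1) * djn1 / jn1
        bn <- -(djn0 - beta * jn0) / (dhn0 - beta * hn0)
        eps <- if (n == 0) 1 else 2
        s <- s + eps * (-1)^n * bn
      }
      K[, j] <- (2 / (pi * k0)) * Mod(s)^2
    }
  }
  structure(list(K = K, f_grid = f_grid, d_grid = d_grid,
                 acoustics = acoustics,
                 impedance_ratio = z1 / z0, speed_ratio = c1 / c0),
            class = "bsc_kernel")
}

# derivative of Bessel J_n / Y_n with respect to the argument
dbessel <- function(x, n, besfun) {
  if (n == 0) return(-besfun(x, 1))
  0.5 * (besfun(x, n - 1) - besfun(x, n + 1))
}

#' Theoretical backscatter coefficient of a pore-size distribution
#'
#' Incoherent (single-scattering) superposition: the backscatter coefficient
#' is the areal pore density times the kernel-weighted average of the
#' cross-section over the diameter distribution,
#' \deqn{BSC(f) = \rho_A \sum_j K(f, d_j)\, p(d_j)\, \Delta d_j.}
#'
#' @param kernel A [build_kernel()] result.
#' @param dist A `pore_size_distribution` (see [new_pore_size_distribution()])
#'   defined on the kernel's diameter grid.
#' @return Numeric vector `BSC(f)` on the kernel frequency grid
#'   (1/(mm * unit angle)).
#' @export
theoretical_bsc <- function(kernel, dist) {
  stopifnot(inherits(kernel, "bsc_kernel"),
            inherits(dist, "pore_size_distribution"))
  if (length(dist$d_grid) != length(kernel$d_grid) ||
      max(abs(dist$d_grid - kernel$d_grid)) > 1e-9 * max(kernel$d_grid))
    fail("distribution diameter grid does not match the kernel grid")
  w <- grid_weights(kernel$d_grid)
  as.numeric(kernel$K %*% (dist$density * w)) * dist$areal_density
}

# trapezoid integration weights for an arbitrary sorted grid
grid_weights <- function(g) {
  n <- length(g)
  if (n == 1) return(1)
  w <- numeric(n)
  w[1] <- (g[2] - g[1]) / 2
  w[n] <- (g[n] - g[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (g[3:n] - g[1:(n - 2)]) / 2
  w
}
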