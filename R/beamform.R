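#' Reconstruct compound envelope images from an RF dataset
#'
#' Envelope-detects every (receive-focused) scanline, scan-converts the
#' three steered frames to a common depth/lateral grid and averages them
#' (spatial compounding), separately for every sweep tilt. Depth is
#' water-equivalent (time of flight converted with the coupling sound
#' speed), which is exact above the bone surface where the surface
#' detection operates.
#'
#' @param rf An [synthesize_rf()] `rf_dataset`.
#' @param depth_range Optional depth window (mm) to reconstruct; `NULL`
#'   reconstructs the full depth axis.
#' @param steering Optional indices of the steering frames to compound
#'   (default: all).
#' @return Object of class `compound_image`: `envelope` array
#'   (depth x lateral x tilt), `depth_mm`, `lateral_mm`, `pixel_mm`,
#'   `steering_angles`, `sweep_tilts`.
#' @export
beamform_compound <- function(rf, depth_range = NULL, steering = NULL) {
  stopifnot(inherits(rf, "rf_dataset"))
  geom <- rf$geometry
  dims <- dim(rf$samples)
  if (dims[2] != geom$n_elements ||
      dims[3] != length(geom$steering_angles) ||
      dims[4] != length(geom$sweep_tilts))
    fail("sample array shape %s does not match the acquisition geometry",
         paste(dims, collapse = "x"))
  cw <- rf$acoustics$coupling_speed / 1000     # mm/us
  fs <- rf$sampling_rate
  nt <- dims[1]
  xl <- scanline_positions(geom)
  dz <- cw / (2 * fs)
  depth <- (0:(nt - 1)) * dz
  if (!is.null(depth_range)) {
    keep_z <- which(depth >= depth_range[1] & depth <= depth_range[2])
    if (length(keep_z) < 8) fail("depth_range too narrow")
    depth <- depth[keep_z]
  } else keep_z <- seq_len(nt)
  nz_out <- length(keep_z)
  env_out <- array(0, dim = c(nz_out, geom$n_elements, dims[4]))
  for (it in seq_len(dims[4])) {
    acc <- matrix(0, nz_out, geom$n_elements)
    wacc <- matrix(0, nz_out, geom$n_elements)
    for (is in (steering %||% seq_len(dims[3]))) {
      th <- geom$steering_angles[is] * pi / 180
      env <- envelope_mat(rf$samples[, , is, it])
      # pixel (z, x) <- steered ray through x - z*tan(th) at range z/cos(th)
      ridx <- (2 * (depth / cos(th)) / cw) * fs + 1      # fractional sample
      ridx_lo <- floor(ridx); rfrac <- ridx - ridx_lo
      valid_r <- ridx_lo >= 1 & ridx_lo < nt
      shift <- depth * tan(th) / geom$pitch              # in line units
      for (ix in seq_len(geom$n_elements)) {
        lidx <- ix - shift
        lidx_lo <- floor(lidx); lfrac <- lidx - lidx_lo
        ok <- valid_r & lidx_lo >= 1 & lidx_lo < geom$n_elements
        if (!any(ok)) next
        v <- (1 - rfrac[ok]) * ((1 - lfrac[ok]) * env[cbind(ridx_lo[ok], lidx_lo[ok])] +
                                lfrac[ok] * env[cbind(ridx_lo[ok], lidx_lo[ok] + 1L)]) +
             rfrac[ok] * ((1 - lfrac[ok]) * env[cbind(ridx_lo[ok] + 1L, lidx_lo[ok])] +
                          lfrac[ok] * env[cbind(ridx_lo[ok] + 1L, lidx_lo[ok] + 1L)])
        acc[ok, ix] <- acc[ok, ix] + v
        wacc[ok, ix] <- wacc[ok, ix] + 1
      }
    }
    env_out[, , it] <- acc / pmax(wacc, 1)
  }
  structure(list(envelope = env_out, depth_mm = depth, lateral_mm = xl,
                 pixel_mm = c(dz, geom$pitch),
                 steering_angles = geom$steering_angles,
                 sweep_tilts = geom$sweep_tilts),
            class = "compound_image")
}
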