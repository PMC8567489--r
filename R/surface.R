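#' Detect and reconstruct the periosteal bone surface
#'
#' Per sweep tilt and scanline, the surface is the first envelope maximum
#' above an adaptive threshold inside the user-supplied ROI gate (ROI
#' selection is the one manual step of the processing chain). The detected
#' depths are smoothed across scanlines with a cross-validated smoothing
#' spline; the local in-plane inclination follows from the smoothed surface
#' gradient and the out-of-plane inclination from the sweep tilt angle.
#' Scanlines are flagged as usable for the reference (surface-reflection)
#' spectrum when the total beam inclination is within 10 degrees and for
#' subsurface backscatter analysis within 30 degrees.
#'
#' @param img A [beamform_compound()] `compound_image`.
#' @param roi List with `x = c(x0, x1)` lateral range (mm) and
#'   `z = c(z0, z1)` depth gate (mm).
#' @param threshold_frac Adaptive threshold as a fraction of the ROI-wide
#'   envelope maximum of each tilt frame.
#' @param ref_max_incl,bs_max_incl Inclination limits (degrees) for
#'   reference and backscatter acceptance.
#' @return Object of class `surface_map`: data frame `map` with columns
#'   tilt index/angle, line, lateral position, raw and smoothed surface
#'   depth (mm), inclination (degrees), and acceptance flags.
#' @export
detect_surface <- function(img, roi, threshold_frac = 0.3,
                           ref_max_incl = 10, bs_max_incl = 30) {
  stopifnot(inherits(img, "compound_image"))
  if (is.null(roi$x) || is.null(roi$z)) fail("roi must supply x and z ranges")
  lines_in <- which(img$lateral_mm >= roi$x[1] & img$lateral_mm <= roi$x[2])
  zsel <- which(img$depth_mm >= roi$z[1] & img$depth_mm <= roi$z[2])
  if (length(lines_in) < 2 || length(zsel) < 3) fail("ROI too small")
  ntilt <- dim(img$envelope)[3]
  out <- vector("list", ntilt)
  for (it in seq_len(ntilt)) {
    frame <- img$envelope[zsel, lines_in, it, drop = FALSE]
    thr <- threshold_frac * max(frame)
    z0 <- rep(NA_real_, length(lines_in))
    for (q in seq_along(lines_in)) {
      e <- frame[, q, 1]
      above <- which(e > thr)
      if (!length(above)) next
      # first local maximum above threshold
      k <- above[1]
      while (k < length(e) && e[k + 1] > e[k]) k <- k + 1
      z0[q] <- img$depth_mm[zsel[k]]
    }
    found <- !is.na(z0)
    if (mean(found) < 0.5)
      fail("surface not found: echo above threshold in only %.0f%% of scanlines (tilt %g deg)",
           100 * mean(found), img$sweep_tilts[it])
    x <- img$lateral_mm[lines_in]
    sp <- stats::smooth.spline(x[found], z0[found], cv = TRUE,
                               all.knots = FALSE)
    z_s <- stats::predict(sp, x)$y
    slope <- stats::predict(sp, x, deriv = 1)$y
    incl_in <- atan(slope) * 180 / pi
    incl <- sqrt(incl_in^2 + img$sweep_tilts[it]^2)
    out[[it]] <- data.frame(
      tilt_idx = it, tilt_deg = img$sweep_tilts[it],
      line = lines_in, x = x, z_raw = z0, z0 = z_s,
      inclination = incl, incl_inplane = incl_in,
      accept_ref = found & abs(incl) <= ref_max_incl,
      accept_bs = found & abs(incl) <= bs_max_incl)
  }
  map <- do.call(rbind, out)
  map$accept_ref <- map$accept_ref & map$accept_bs  # reference subset of backscatter
  structure(list(map = map, roi = roi,
                 ref_max_incl = ref_max_incl, bs_max_incl = bs_max_incl),
            class = "surface_map")
}
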