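#' Segment the cortical compartment of a micro-CT volume
#'
#' Thresholds at half the matrix vBMD, applies a morphological closing,
#' keeps the largest connected component, and derives the periosteal
#' contour by hull filling. The endosteal (marrow) cavity is the largest
#' enclosed background component; the filled cortex is the periosteal
#' region minus the marrow cavity, i.e. the cortical compartment with the
#' pores filled. Because the synthetic anatomy is prismatic along the
#' scan axis, masks are built from the slice-averaged volume and shared by
#' all slices; the per-slice mode of the downstream operations consumes
#' them unchanged.
#'
#' @param vol A [synthesize_microct()] `microct_volume`.
#' @param roi_sector Optional angular range (degrees, length 2) selecting
#'   an anteromedial-style region of interest about the section centroid.
#' @param threshold_frac Bone threshold as a fraction of matrix vBMD.
#' @param closing_um Diameter (um) of the disc kernel used for closing.
#' @return Object of class `cortex_masks`: logical matrices `bone`,
#'   `periosteal`, `endosteal`, `cortical` (= periosteal minus endosteal),
#'   `roi`, pixel size, and the centroid.
#' @export
segment_cortex <- function(vol, roi_sector = NULL, threshold_frac = 0.5,
                           closing_um = 300) {
  stopifnot(inherits(vol, "microct_volume"))
  vox <- vol$voxel_um / 1000
  msl <- apply(vol$data, c(1, 2), mean)
  thr <- threshold_frac * vol$calibration$matrix_vbmd
  bone <- msl > thr
  if (!any(bone)) fail("no bone above threshold")
  r_px <- max(3, 2 * round(closing_um / vol$voxel_um / 2) + 1)
  kern <- EBImage::makeBrush(r_px, shape = "disc")
  bone_c <- EBImage::closing(bone, kern) > 0
  lab <- EBImage::bwlabel(bone_c)
  keep <- which.max(tabulate(lab[lab > 0]))
  bone_c <- lab == keep
  peri <- EBImage::fillHull(bone_c) > 0
  cav <- peri & !bone_c
  endo <- matrix(FALSE, nrow(cav), ncol(cav))
  if (any(cav)) {
    clab <- EBImage::bwlabel(cav)
    sizes <- tabulate(clab[clab > 0])
    # the marrow cavity is the largest enclosed background region, and
    # only counts as such when clearly larger than pore-scale holes
    if (length(sizes) && max(sizes) * vox^2 > 1) {
      endo <- clab == which.max(sizes)
    }
  }
  cortical <- peri & !endo
  bone_mask <- bone & cortical
  ctr <- c(mean(row(peri)[peri]), mean(col(peri)[peri]))
  roi <- cortical
  if (!is.null(roi_sector)) {
    ang <- atan2(col(peri) - ctr[2], row(peri) - ctr[1]) * 180 / pi
    roi <- cortical & ang >= roi_sector[1] & ang <= roi_sector[2]
    if (!any(roi)) fail("ROI sector contains no cortex")
  }
  structure(list(bone = bone_mask, periosteal = peri, endosteal = endo,
                 cortical = cortical, roi = roi,
                 voxel_um = vol$voxel_um, centroid = ctr,
                 threshold = thr),
            class = "cortex_masks")
}

# 3x3 maximum filter (replicated edges)
max3 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- m
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    sh <- m[pmin(pmax(seq_len(n1) + dx, 1), n1),
            pmin(pmax(seq_len(n2) + dy, 1), n2)]
    out <- pmax(out, sh)
  }
  out
}

#' Cortical thickness by the distance-transform ridge
#'
#' Twice the Euclidean distance transform evaluated on its ridge (the
#' locus of largest inscribed circles), averaged over the mask and
#' corrected for the half-voxel offset of center-to-center distances.
#'
#' @param masks A [segment_cortex()] result.
#' @param roi Use the ROI mask instead of the full cortex.
#' @return Thickness in mm.
#' @export
cortical_thickness <- function(masks, roi = FALSE) {
  stopifnot(inherits(masks, "cortex_masks"))
  m <- if (roi) masks$roi else masks$cortical
  if (!any(m)) fail("empty mask")
  dt <- EBImage::distmap(m)
  ridge <- m & dt >= max3(dt) - 1e-9
  (2 * mean(dt[ridge]) - 1) * masks$voxel_um / 1000
}

#' Burghardt-style pore segmentation, porosity, and pore density
#'
#' Pores are below-threshold voxels inside the filled cortex. The voxel
#' porosity Ct.Po_BH is evaluated over all slices; pore components (and
#' the pore density Ct.Po.Dn, components per cortical area) are labelled
#' on the slice-averaged section, where a component must contain at least
#' `min_voxels` voxels once extruded through the slices (8-connectivity
#' in-plane, which restricted to prismatic structures equals
#' 26-connectivity in 3-D).
#'
#' @param vol A `microct_volume`.
#' @param masks A `cortex_masks`.
#' @param threshold_frac Pore threshold as a fraction of matrix vBMD.
#' @param min_voxels Minimum 3-D component size (voxels).
#' @param roi Restrict to the ROI sector.
#' @return Object of class `pore_segmentation`: `ct_po_bh` (%),
#'   `ct_po_dn` (1/mm^2), `labels` (component label matrix), `n_pores`,
#'   `pore_mask`.
#' @export
pore_segmentation_bh <- function(vol, masks, threshold_frac = 0.5,
                                 min_voxels = 2, roi = FALSE) {
  stopifnot(inherits(vol, "microct_volume"), inherits(masks, "cortex_masks"))
  region <- if (roi) masks$roi else masks$cortical
  thr <- threshold_frac * vol$calibration$matrix_vbmd
  nsl <- dim(vol$data)[3]
  pore_frac <- vapply(seq_len(nsl), function(s) {
    sl <- vol$data[, , s]
    sum(sl < thr & region) / sum(region)
  }, numeric(1))
  msl <- apply(vol$data, c(1, 2), mean)
  pore_mask <- region & msl < thr
  lab <- EBImage::bwlabel(pore_mask)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes * nsl < min_voxels)
    if (length(small)) {
      lab[lab %in% small] <- 0
      lab <- EBImage::bwlabel(lab > 0)
    }
  }
  n_pores <- max(lab)
  area_mm2 <- sum(region) * (masks$voxel_um / 1000)^2
  structure(list(ct_po_bh = 100 * mean(pore_frac),
                 ct_po_dn = n_pores / area_mm2,
                 labels = lab, n_pores = n_pores,
                 pore_mask = lab > 0, threshold = thr, roi = roi),
            class = "pore_segmentation")
}

#' Local porosity map from the vBMD distribution
#'
#' Slides a cubic window over the cortex and converts the window's vBMD
#' statistics into a local porosity through a pluggable calibration rule.
#' The default rule is the partial-volume relation
#' `Ct.Po_local = 100 (1 - mean(vBMD) / matrix vBMD)`, which captures the
#' porosity contributed by pores well below the voxel size. The map is
#' evaluated at voxels whose full window lies inside the filled cortex.
#'
#' @param vol A `microct_volume`.
#' @param masks A `cortex_masks`.
#' @param window_mm Cubic window edge length (mm), default 0.5.
#' @param calibration Function `(mean_vbmd, sd_vbmd, matrix_vbmd) ->
#'   porosity (%)`.
#' @param roi Restrict to the ROI sector.
#' @return Object of class `porosity_map`: `values` (vector, %), `map`
#'   (mid-slice matrix, NA outside), `center_mask`.
#' @export
local_porosity_map <- function(vol, masks, window_mm = 0.5,
                               calibration = NULL, roi = FALSE) {
  stopifnot(inherits(vol, "microct_volume"), inherits(masks, "cortex_masks"))
  if (is.null(calibration))
    calibration <- function(mu, sd, matrix_vbmd) 100 * (1 - mu / matrix_vbmd)
  vox <- vol$voxel_um / 1000
  w_px <- max(1, round(window_mm / vox))
  region <- if (roi) masks$roi else masks$cortical
  dt <- EBImage::distmap(region)
  # a cubic window reaches half its diagonal into the corners
  centers2d <- region & dt > w_px / sqrt(2) + 1
  if (!any(centers2d))
    fail("window (%g mm) larger than the cortex", window_mm)
  nsl <- dim(vol$data)[3]
  wz <- min(nsl, w_px)
  # in-plane box mean per slice (separable running means), then z average
  box1 <- function(m, k) {
    n <- nrow(m)
    cs <- rbind(0, apply(m, 2, cumsum))
    lo <- k %/% 2; hi <- k - 1 - lo
    i1 <- pmin(seq_len(n) + hi, n); i0 <- pmax(seq_len(n) - lo, 1)
    (cs[i1 + 1, , drop = FALSE] - cs[i0, , drop = FALSE]) / (i1 - i0 + 1)
  }
  box <- function(m, k) t(box1(t(box1(m, k)), k))
  mu_sl <- lapply(seq_len(nsl), function(s) box(vol$data[, , s], w_px))
  mu2_sl <- lapply(seq_len(nsl), function(s) box(vol$data[, , s]^2, w_px))
  z0 <- max(1, (nsl - wz) %/% 2 + 1)
  zz <- z0:(z0 + wz - 1)
  mu <- Reduce(`+`, mu_sl[zz]) / wz
  mu2 <- Reduce(`+`, mu2_sl[zz]) / wz
  sdv <- sqrt(pmax(mu2 - mu^2, 0))
  pmap <- calibration(mu, sdv, vol$calibration$matrix_vbmd)
  pmap[!centers2d] <- NA_real_
  structure(list(values = pmap[centers2d], map = pmap,
                 center_mask = centers2d, window_mm = window_mm),
            class = "porosity_map")
}

#' Pore diameter distribution from a pore segmentation
#'
#' Per labelled component, the diameter of the largest inscribed circle
#' via the Euclidean distance transform (half-voxel corrected), in um.
#'
#' @param seg A [pore_segmentation_bh()] result.
#' @param voxel_um Voxel size (um).
#' @return Numeric vector of component diameters (um); length zero with a
#'   warning attribute when no pores were segmented.
#' @export
pore_diameter_dist <- function(seg, voxel_um) {
  stopifnot(inherits(seg, "pore_segmentation"))
  if (seg$n_pores == 0) {
    out <- numeric(0)
    attr(out, "empty") <- TRUE
    return(out)
  }
  dt <- EBImage::distmap(seg$pore_mask)
  vapply(seq_len(seg$n_pores), function(k) {
    sel <- seg$labels == k
    # raw inscribed-circle diameter is quantized to the voxel grid; the
    # +0.5 voxel offset compensates the raster bias of discs (verified
    # against rasterized discs of known diameter)
    d_dt <- (2 * max(dt[sel]) + 0.5) * voxel_um
    # for a near-circular section the area-equivalent diameter equals
    # the inscribed-circle diameter but resolves below the voxel; use it
    # when the two agree, keep the distance transform for irregular or
    # merged components where the inscribed circle is the smaller one.
    # +1 voxel compensates the undercount of the 50%-coverage threshold
    # on convex boundaries (measured on rasterized discs)
    d_area <- 2 * sqrt((sum(sel) + 1) / pi) * voxel_um
    if (d_area < d_dt + 1.5 * voxel_um) d_area else d_dt
  }, numeric(1))
}

#' Moment and quantile statistics of a distribution sample
#'
#' Sample mean, SD, variance, skewness, non-excess kurtosis (Gaussian data
#' give 3), and the 10/90% quantiles by linear interpolation.
#'
#' @param x Numeric sample with at least `min_n` observations.
#' @param min_n Minimum sample size.
#' @return Named list: mean, sd, var, skewness, kurtosis, q10, q90, n.
#' @export
moment_stats <- function(x, min_n = 8) {
  x <- x[is.finite(x)]
  if (length(x) < min_n)
    fail("too few observations (%d < %d)", length(x), min_n)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  q <- stats::quantile(x, c(0.1, 0.9), names = FALSE, type = 7)
  list(mean = m, sd = stats::sd(x), var = stats::var(x),
       skewness = m3 / m2^1.5, kurtosis = m4 / m2^2,
       q10 = q[1], q90 = q[2], n = length(x))
}

#' Full custom morphometry of a micro-CT volume
#'
#' Runs cortex segmentation, cortical thickness, Burghardt porosity and
#' pore density, the local porosity map, and the pore-diameter and vBMD
#' distributions with their moment statistics, for the full cross-section
#' and (when a sector is given) a site-matched ROI.
#'
#' @param vol A `microct_volume`.
#' @param roi_sector Optional angular range (degrees) for the ROI.
#' @param window_mm Local-porosity window (mm).
#' @return Object of class `morphometry_result`: per region (`full`,
#'   `roi`) a list with `ct_th`, `ct_po_bh`, `ct_po_dn` and moment
#'   statistics of `ct_po_d`, `ct_po_dm`, `ct_bmd_d`.
#' @export
analyze_microct <- function(vol, roi_sector = NULL, window_mm = 0.5) {
  masks <- segment_cortex(vol, roi_sector = roi_sector)
  regions <- list(full = FALSE)
  if (!is.null(roi_sector)) regions$roi <- TRUE
  out <- lapply(regions, function(use_roi) {
    seg <- pore_segmentation_bh(vol, masks, roi = use_roi)
    pmap <- local_porosity_map(vol, masks, window_mm = window_mm,
                               roi = use_roi)
    dm <- pore_diameter_dist(seg, vol$voxel_um)
    region <- if (use_roi) masks$roi else masks$cortical
    msl <- apply(vol$data, c(1, 2), mean)
    bmd_vals <- msl[region & masks$bone]
    list(ct_th = cortical_thickness(masks, roi = use_roi),
         ct_po_bh = seg$ct_po_bh,
         ct_po_dn = seg$ct_po_dn,
         ct_po_d = moment_stats(pmap$values),
         ct_po_dm = if (length(dm) >= 8) moment_stats(dm) else NULL,
         ct_bmd_d = moment_stats(bmd_vals),
         n_pores = seg$n_pores)
  })
  structure(list(regions = out, masks = masks, voxel_um = vol$voxel_um),
            class = "morphometry_result")
}
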