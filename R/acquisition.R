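#' Pulse-echo acquisition geometry
#'
#' Describes the compound B-mode volume scan: a slightly focused beam from a
#' 16-element subaperture of a 128-element linear array is swept across the
#' array one element at a time, the scan is repeated at three beam steering
#' angles, and a motor sweeps the imaging plane through a range of tilt
#' angles perpendicular to it. The imaging plane contains the bone
#' cross-section; the sweep moves along the bone axis.
#'
#' @param n_elements Number of array elements (and scanlines), default 128.
#' @param subaperture Transmit subaperture size (elements).
#' @param pitch Element pitch (mm).
#' @param steering_angles In-plane beam steering angles (degrees).
#' @param sweep_tilts Motor tilt angles of the imaging plane (degrees).
#' @param sampling_rate Sampling rate (MHz).
#' @param center_frequency Pulse center frequency (MHz).
#' @param bandwidth_sigma Gaussian spectral half-width of the pulse (MHz);
#'   the default keeps the 4-9 MHz analysis band inside the transducer band.
#' @param focus_depth Focus depth below the bone surface (mm).
#' @param standoff Soft-tissue/coupling standoff thickness (mm).
#' @param beamwidth Effective -6 dB beam width at the focus (mm); sets which
#'   pores contribute to a scanline and the backscatter normalization.
#' @param n_samples Number of time samples per A-line.
#' @return Object of class `acquisition_geometry`.
#' @export
acquisition_geometry <- function(n_elements = 128, subaperture = 16,
                                 pitch = 0.3,
                                 steering_angles = c(-10, 0, 10),
                                 sweep_tilts = seq(-7, 7, by = 1),
                                 sampling_rate = 40,
                                 center_frequency = 6.5,
                                 bandwidth_sigma = 1.8,
                                 focus_depth = 1,
                                 standoff = 5,
                                 beamwidth = 0.6,
                                 n_samples = 448) {
  stopifnot(n_elements >= 1, pitch > 0, sampling_rate > 0,
            center_frequency > 0, n_samples > 16, beamwidth > 0)
  structure(list(n_elements = as.integer(n_elements),
                 subaperture = as.integer(subaperture),
                 pitch = pitch,
                 steering_angles = steering_angles,
                 sweep_tilts = sweep_tilts,
                 sampling_rate = sampling_rate,
                 center_frequency = center_frequency,
                 bandwidth_sigma = bandwidth_sigma,
                 focus_depth = focus_depth,
                 standoff = standoff,
                 beamwidth = beamwidth,
                 n_samples = as.integer(n_samples)),
            class = "acquisition_geometry")
}

# lateral scanline positions (mm), centered on the aperture
scanline_positions <- function(geom) {
  (seq_len(geom$n_elements) - (geom$n_elements + 1) / 2) * geom$pitch
}
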