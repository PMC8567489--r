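---
title: "Cortical backscatter: models, estimators, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical backscatter: models, estimators, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette describes the science implemented in `cortbs`: the synthetic
models of cortical-bone pore microstructure and its ultrasonic and
micro-CT signatures, the cortical backscatter (CortBS) processing chain,
the pore-size inversion, the site-matched morphometry, and the
discrimination statistics — together with the numerical choices, the
design decisions made where the design was genuinely open, and what the
validation studies do and do not demonstrate.

## The pore microstructure model

Cortical bone is perfused by a network of quasi-parallel vascular (
Haversian) canals. Normal remodeling leaves canals of roughly 30 um
diameter; unbalanced remodeling leaves incompletely refilled cavities
that merge into much larger pores, up to several hundred um, and most of
the diagnostic information targeted here lies in the upper tail of the
pore-diameter distribution.

`diameter_mixture()` models diameters as a two-component lognormal
mixture: a baseline component with median 30 um (log-SD 0.35), and a
pathological tail (default weight 0.03, median 120 um, log-SD 0.40,
reaching ~400 um). The tail defaults were calibrated once so that the
pipeline's recovered descriptors fall in the ranges reported for
postmenopausal cohorts in vivo (peak near 35-50 um, Q90 below ~65 um for
the attenuation-weighted part of the distribution); heavier tails
dominate the backscatter (the cross-section grows as the fourth power of
diameter) and push the recovered Q90 far beyond anything reported in
vivo. With any non-zero tail the *number-weighted* Q90 recovered from
backscatter remains tail-inflated relative to in-vivo descriptor ranges
— scattering weights pores by d^4, and no regularized inversion can
fully undo that weighting; this is a known limitation discussed below.

`sample_pore_population()` places pores as straight circular cylinders
along the bone axis (2.5-D geometry) by dart throwing with a hard-core
minimum spacing (default 80 um, rejection capped at 10^4 attempts). The
2.5-D choice matches the cylindrical-scatterer kernel used for the
inversion; out-of-plane tortuosity is deliberately ignored.

Default material properties (`bone_acoustics()`): matrix speed 3800 m/s,
density 1.9 g/cm^3, matrix vBMD 1100 mg HA/cm^3; pore fluid 1500 m/s,
1.0 g/cm^3; coupling medium 1540 m/s. These are conventional textbook
values for mineralized cortical tissue, not measurements of any cohort,
and all are configurable.

## The ultrasonic forward model

`synthesize_rf()` emulates the compound volume scan of a 128-element
linear array: a focused beam stepped across the aperture, repeated at
three steering angles (-10, 0, +10 degrees), with a motor sweeping the
imaging plane through +-7 degrees along the bone axis. Each A-line is

* a specular surface echo with the planar reflection coefficient of the
  coupling/bone impedance contrast, attenuated by a Gaussian obliquity
  lobe (half-width 30 degrees) when the beam is inclined to the surface
  normal, and
* one echo per insonified pore, with amplitude proportional to
  sqrt(sigma_b(f, d)) from the cylinder scattering kernel, a uniform
  random phase, the two-way delay, and two-way amplitude decay
  10^(-alpha(f) 2z/20) with alpha(f) = alpha0 + alphaf f (dB/mm,
  one-way),

plus white noise at a configured SNR. Pores within half an effective
beam width (0.6 mm) of the (steered) beam axis contribute. Echo phases
are drawn independently per tilt, steering, and scanline, and each sweep
tilt insonifies a fresh pore realization (`tilt_decorrelate = TRUE`):
real pore networks decorrelate along the bone axis, and without this the
single simulated cross-section would make all frames fully correlated,
which is both unphysical and misleadingly pessimistic for averaging.
Refraction at the surface, phase aberration, and multiple scattering are
not modeled.

## The processing chain

`beamform_compound()` envelope-detects each receive-focused line,
scan-converts the steered frames, and averages them per sweep tilt.
`detect_surface()` finds, per scanline, the first envelope maximum above
an adaptive threshold inside the user ROI (the one manual step), smooths
the surface with a cross-validated smoothing spline, and derives the
local beam inclination from the in-plane gradient plus the sweep tilt;
lines are accepted for the reference spectrum within 10 degrees and for
backscatter analysis within 30 degrees.

`compute_nds()` forms the normalized depth-dependent spectrum: 1-mm
Hann-gated short-time spectra slide from the detected surface downward
(75% overlap, gate centers on a 0.25-mm grid), normalized by the
inclination-corrected mean surface-reflection spectrum, in dB. Three
robustness elements matter in practice and are on by default:

* *surface-clutter removal* — the surface-aligned mean waveform is
  scaled to each line's surface peak and subtracted before gating, so
  ringdown does not leak into the shallow gates;
* *noise-floor subtraction* — pre-surface gated noise spectra are
  subtracted from the pooled backscatter powers (and from the long-gate
  band spectrum); cells not clearly above the floor are masked;
* *level gating* — lines whose gate RMS is below twice the line's
  pre-surface noise RMS do not contribute, and cells with fewer than 4
  contributing lines are masked. The `quality_score()` is the retained
  fraction of candidate line-depth cells, gated at 77%.

`estimate_attenuation()` interprets the 1-3 mm analysis range as the
range of *gate centers* (a gate "at 1 mm" spans 0.5-1.5 mm), which
doubles the usable depth lever relative to a fully-inside reading. A
1-mm gate in bone lasts ~0.5 us, so its spectral resolution (~2-3 MHz)
is comparable to the 4-9 MHz band: each analysis bin reports a smeared
average of neighboring frequencies. The default estimator
(`method = "model"`) therefore fits the gate-window forward model: the
underlying band shape S(f) is recovered by parametric deconvolution (a
log-cubic fit through the long-gate spectrum's window model over the
pulse support), and the attenuation slope is the value whose
window-model frequency-by-depth interaction best matches the NDS after
projecting out additive bin and depth effects. Those projections absorb
the reference spectrum, alpha0's depth decay, and the realized
scatterer depth profile, so `Ct.alphaf` is estimated from the
interaction alone; `Ct.alpha0` then follows from the per-bin slopes
placed at their effective (spectral-centroid) frequencies. The plain
per-bin/line-fit route of the two-stage textbook estimator is available
as `method = "two-stage"`.

`estimate_bsc()` uses reference substitution with the documented
gate/beam normalization `C = 1/(beamwidth * gate * mean(w^2))` and a
dimensionless smearing correction from the same deconvolved band shape
(the specular reference is smeared at the amplitude level and is
deconvolved with its own model). Diffraction and focusing are assumed to
cancel between the backscatter and reference paths; the absolute BSC
scale is therefore trustworthy only to a geometry factor of order one,
while the spectral shape — which is what the inversion uses — is
validated to better than 10% RMS.

## Pore-size inversion

`build_kernel()` implements the exact modal (cylindrical-harmonic)
series for a fluid cylinder in a fluid host: continuity of pressure and
normal velocity at the pore wall, series truncated at
`max(10, ceil(ka) + 4)` terms, backscatter direction. Matrix shear is
neglected; the model is linear in the size distribution, and in the
long-wavelength limit reproduces the two-dimensional Rayleigh law
sigma_b ~ k^3 a^4 (verified to 2%). Over 4-9 MHz and 5-400 um, ka spans
~0.1-3, so both Rayleigh and resonance regimes occur.

`invert_distribution()` solves the non-negative, smoothness-regularized
least-squares problem on 64 log-spaced diameter bins over 5-400 um,
with second differences of the density (plus first-difference edge rows)
as the roughness penalty and a light ridge (one tenth of the smoothing
weight) that suppresses probability mass in bins the kernel is
essentially blind to — without it, NNLS parks arbitrary mass at the
smallest diameters to absorb systematic residuals. The regularization
weight follows the discrepancy principle (largest lambda whose residual
stays within the expected noise norm) with a fixed-lambda mode for
reproducibility. The solution is scale-equivariant: scaling the BSC
rescales only the areal-density scale, never the normalized density or
its descriptors. Descriptors follow the reported parameter family:
peak (ties toward the smallest diameter), Q10/Q90 by linear CDF
interpolation, and the outermost interpolated half-maximum crossings.
The density is number-weighted; whether in-vivo descriptor tables are
number- or volume-weighted is not established, and a volume-weighted
reading would change the tail emphasis.

## Micro-CT synthesis and morphometry

`synthesize_microct()` wraps the pore slab onto a cortical annulus
sector (lateral coordinate to arc length, depth to radial depth below
the periosteum) and rasterizes the cylinders at 60.7-um isotropic voxels
with an area-coverage partial-volume model, so sub-voxel pores lower
voxel vBMD in proportion to covered area instead of vanishing; a
Gaussian in-plane PSF (default 45 um) and additive noise (default 20 mg
HA/cm^3) follow. Pores below ~90-120 um are unresolved (no voxel falls
below the segmentation threshold) but remain visible to density-based
statistics — exactly the regime the local-porosity calibration targets.

The morphometry follows the custom HR-pQCT protocol: threshold at half
matrix vBMD, morphological closing, largest component, hull filling;
the filled cortex is the periosteal region minus the marrow cavity.
`cortical_thickness()` doubles the distance-transform ridge (half-voxel
corrected). `pore_segmentation_bh()` labels below-threshold voxels
inside the filled cortex (minimum 2 voxels, 8-connectivity in-plane,
which for the prismatic synthetic anatomy equals 26-connectivity in
3-D); because that anatomy is identical across slices, masks and labels
are built on the slice-averaged section and porosity is averaged over
slices — a per-slice specialization of the 3-D protocol that is exact
here. `local_porosity_map()` slides a 0.5-mm window over the cortex and
converts window statistics to local porosity with a pluggable
calibration whose default is the partial-volume rule
`100 (1 - mean(vBMD)/matrix vBMD)`; the published calibration
coefficients for real scanners are not public, so the rule is the
structural stand-in and its ~3.4% absolute-error budget is verified
against the generator's ground truth. Component diameters use the
distance transform with a +0.5-voxel disc-raster correction calibrated
on rasterized discs of known diameter. `moment_stats()` reports
non-excess kurtosis (Gaussian data give 3, matching the conventions of
published morphometry tables).

## Cohort synthesis and statistics

`generate_cohort()` draws per-group multivariate-normal cohorts whose
means and SDs reproduce the published group statistics of a
postmenopausal fracture study (29 fractured / 26 non-fractured;
attenuation intercept 2.34 +- 0.40 vs 1.96 +- 0.48 dB/mm, slope 0.11 +-
0.06 vs 0.16 +- 0.06 dB/MHz/mm, and the corresponding DXA, HR-pQCT and
pore-descriptor blocks), with block-diagonal correlation (0.3 within a
modality, 0 across — the true structure is unreported, and this single
knob is configurable). BMI is derived from height and weight; vertebral
(18) and other (21) fracture subtypes overlap in 10 subjects; ~15% of
spine T-scores are set missing and never imputed (listwise deletion per
endpoint model).

`pls_fit()` is classical NIPALS PLS1 on autoscaled columns with +-1
class coding for discrimination; `cross_validated_pls()` provides
leave-one-out and stratified 3-fold schemes. For two-class responses the
fold predictions are centered by the training-set mean response: leaving
out a positive lowers the training mean and with it the held-out score,
a composition artifact that otherwise biases the cross-validated AUC
well below 0.5 under the null. Even centered, pooled LOOCV scores retain
a small pessimistic offset (about -0.04 at n = 55), which is why the
null-calibration study reports the leave-pair-out AUC (`lpocv_auc()`),
the unbiased estimator of the cross-validated AUC; both numbers are
returned.

`spa_select()` implements Monte Carlo subwindow variable selection:
each round trains PLS-DA on a random 70% subject subset and a random
half of the candidate variables, recording the out-of-subset error;
per variable, rounds including versus excluding it are compared with a
one-sided rank-sum statistic. The raw p-value of that comparison cannot
control false selection — with thousands of rounds, any noise variable
whose *realized* sample correlation with the labels happens to help
prediction is genuinely detected — so the statistic is calibrated
against shadow variables (two row-permuted copies per candidate,
t-calibrated threshold), which restores the ~5% per-variable false
selection rate while keeping full power at a standardized separation of
1.5. Selection is repeated until two passes agree; sets of two or fewer
variables cannot be subwindowed further and are final.

`roc_metrics()` uses the rank-formula AUC with Hanley-McNeil standard
errors, a Youden-optimal operating point (ties resolved toward higher
specificity), `odds_ratio()` the cross-product ratio with
Haldane-Anscombe correction and Woolf intervals, and `compare_auc()`
the two-sided Hanley-McNeil z-test. Published OR confidence intervals
for the study this emulates are far narrower than Woolf intervals from
the printed counts; their derivation is unknown, so the point OR is the
quantity checked and the interval method here is Woolf.

## Validation studies and their limits

The `study_*()` functions regenerate every validation quantity from
scratch; `scripts/acceptance.R` runs them all and
`tests/testthat/test-acceptance.R` asserts them. Problem sizes are
stated here as the package's own design: the attenuation recovery uses
20 study seeds averaging 10 repositioned acquisitions each at the full
acquisition geometry (a speckle-limited CRLB analysis puts the
single-acquisition slope precision near 13%, so no estimator can reach a
5% median from one scan; averaging repeat acquisitions is the same
remedy the short-term precision protocol uses), on a monodisperse 30-um
reference phantom in the tradition of QUS reference-phantom
calibration. The Q90 recovery inverts noiseless and 5%-noise synthetic
BSCs from a lognormal (median 40 um); morphometry accuracy uses a
noiseless annulus for thickness/porosity, unresolved 30-um pores at 5%
porosity for the local map, and >=140-um pores for the diameter
distribution; the statistics calibration uses 50 label permutations,
20 SPA seeds at 300 Monte Carlo rounds (the production default of
10,000 adds nothing at 10 candidates), and 50 synthetic cohorts.

What passing these studies shows: the chain is internally consistent —
programmed physics is recovered through simulation, beamforming,
detection, spectral estimation, inversion, and morphometry, and the
statistical machinery is calibrated under its own assumptions. What it
does not show: performance on real tissue. The generator's pores are
straight parallel cylinders with fully decorrelated speckle across
frames; real pore networks branch, tilt, and correlate; real bone adds
absorption heterogeneity, cortical curvature, soft-tissue aberration,
and probe-contact variability, none of which are modeled. The clinical
discrimination numbers reproduced here (worked confusion matrices,
binormal effect-size AUC, cohort-level LOOCV AUC ranges) validate
arithmetic and plausibility against published group statistics, not
clinical performance.

## Reproducibility

Every stochastic function takes a `seed`; fixed seeds give bit-identical
populations, RF volumes, CT volumes, and cohorts. `run_pipeline()`
chains all stages under one master seed, records a provenance hash of
the canonicalized configuration, excludes measurements whose quality
score falls below 77%, and `write_container()`/`read_container()`
round-trip all outputs through a plain-text (JSON/CSV) plus TIFF
container, byte-identically on rewrite.
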