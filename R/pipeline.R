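CONTAINER_VERSION <- "cortbs-bundle-1"

#' Default pipeline configuration
#'
#' One nested list with per-module blocks; every analysis constant of the
#' processing chain (4-9 MHz band, 1-3 mm depth range, +-10/+-30 degree
#' inclination gates, 77% quality threshold, 3 PLS components, 60.7 um
#' voxels) lives here. A YAML file with the same structure can be loaded
#' with [load_config()].
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @return Nested list of class `cortbs_config`.
#' @export
cortbs_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    mixture = list(baseline_log_mean = log(30), baseline_log_sd = 0.35,
                   tail_weight = 0.03, tail_log_mean = log(120),
                   tail_log_sd = 0.40, pore_density = 12, hard_core = 80),
    slab_extent = c(40, 5, 4),
    rf = list(alpha0 = 2.0, alphaf = 0.10, snr_db = 30,
              band = c(4, 9), depth_range = c(1, 3),
              quality_threshold = 0.77),
    roi = list(x = c(-18, 18), z = c(3, 8)),
    ct = list(voxel_um = 60.7, n_slices = 24, psf_sigma_um = 45,
              noise_sd = 20, outer_radius = 9,
              roi_sector = c(-45, 45), window_mm = 0.5),
    inversion = list(lambda = "auto", d_min = 5, d_max = 400, n_d = 64),
    cohort = list(n_fx = 29, n_nfx = 26, n_vertebral = 18, n_other = 21,
                  missing_spine_frac = 0.15),
    discrimination = list(endpoints = c("all", "vertebral", "other"),
                          features = "cortbs", ncomp = 3, n_mc = 1000)
  ), class = "cortbs_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file with (a subset of) the [cortbs_config()] blocks;
#'   missing entries take their defaults.
#' @return A validated `cortbs_config`.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- cortbs_config(seed = user$seed %||% 1)
  for (blk in intersect(names(user), names(cfg))) {
    if (is.list(cfg[[blk]]) && is.list(user[[blk]])) {
      for (k in names(user[[blk]])) cfg[[blk]][[k]] <- user[[blk]][[k]]
    } else cfg[[blk]] <- user[[blk]]
  }
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every block against its module's constraints before any
#' computation runs.
#'
#' @param cfg A `cortbs_config`.
#' @return The config, invisibly; errors name the offending block.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, blk, msg) if (!ok) fail("config block '%s': %s", blk, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed", "one integer required")
  m <- cfg$mixture
  chk(m$tail_weight >= 0 && m$tail_weight <= 1, "mixture", "tail_weight in [0,1]")
  chk(m$pore_density > 0, "mixture", "pore_density > 0")
  chk(all(cfg$slab_extent > 0), "slab_extent", "positive lengths")
  chk(cfg$rf$snr_db >= 0, "rf", "snr_db >= 0")
  chk(diff(cfg$rf$band) > 0, "rf", "band increasing")
  chk(diff(cfg$rf$depth_range) > 0, "rf", "depth_range increasing")
  chk(cfg$rf$quality_threshold >= 0 && cfg$rf$quality_threshold <= 1,
      "rf", "quality_threshold in [0,1]")
  chk(cfg$ct$voxel_um > 0, "ct", "voxel_um > 0")
  chk(cfg$ct$psf_sigma_um >= 0, "ct", "psf_sigma_um >= 0")
  chk(cfg$inversion$d_min > 0 && cfg$inversion$d_max > cfg$inversion$d_min,
      "inversion", "diameter bounds positive and increasing")
  chk(cfg$cohort$n_fx > 0 && cfg$cohort$n_nfx > 0, "cohort", "group sizes > 0")
  chk(all(cfg$discrimination$endpoints %in% c("all", "vertebral", "other")),
      "discrimination", "unknown endpoint")
  invisible(cfg)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full simulation-to-statistics pipeline
#'
#' Executes, in dependency order: pore-population sampling, RF synthesis,
#' RF processing (compound beamforming, surface detection, NDS, quality
#' score, attenuation, BSC), pore-size inversion, micro-CT synthesis and
#' morphometry, cohort generation, and PLS-LOOCV fracture discrimination
#' per endpoint. A measurement whose quality score falls below the
#' configured threshold is excluded from the spectral analyses (its
#' attenuation/BSC/distribution outputs are absent, mirroring the
#' quality-gated exclusion of measurements in practice). Any stage failure
#' halts the run with a stage-named error.
#'
#' @param cfg A [cortbs_config()].
#' @return Object of class `result_bundle`: `provenance` (config, hash,
#'   seed, package version), per-stage outputs, and `summary` tables.
#' @export
run_pipeline <- function(cfg = cortbs_config()) {
  validate_config(cfg)
  seeds <- child_seeds(cfg$seed, 8)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      fail("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  mix <- stage("mixture", do.call(diameter_mixture, cfg$mixture))
  pop <- stage("population",
               sample_pore_population(mix, cfg$slab_extent, seed = seeds[1]))
  geom_args <- cfg$rf[intersect(names(cfg$rf),
                                names(formals(acquisition_geometry)))]
  geom <- do.call(acquisition_geometry, geom_args)
  rf <- stage("rf_synthesis",
              synthesize_rf(pop, geom, alpha0 = cfg$rf$alpha0,
                            alphaf = cfg$rf$alphaf, snr_db = cfg$rf$snr_db,
                            seed = seeds[2]))
  img <- stage("beamform", beamform_compound(rf))
  surf <- stage("surface", detect_surface(img, roi = cfg$roi))
  nds <- stage("nds", compute_nds(rf, surf, band = cfg$rf$band))
  qs <- quality_score(surf, nds, threshold = cfg$rf$quality_threshold)
  att <- NULL; bsc <- NULL; dist <- NULL
  if (qs$pass) {
    att <- stage("attenuation",
                 estimate_attenuation(nds, depth_range = cfg$rf$depth_range))
    bsc <- stage("bsc",
                 estimate_bsc(nds, att, reflection_coefficient(pop$acoustics),
                              depth_range = cfg$rf$depth_range))
    dgrid <- exp(seq(log(cfg$inversion$d_min), log(cfg$inversion$d_max),
                     length.out = cfg$inversion$n_d))
    kern <- stage("kernel", build_kernel(nds$freq, dgrid, pop$acoustics))
    dist <- stage("inversion",
                  invert_distribution(bsc, kern,
                                      inversion_config(lambda = cfg$inversion$lambda)))
  }
  ct <- stage("microct",
              synthesize_microct(pop, do.call(ct_params,
                cfg$ct[c("voxel_um", "n_slices", "psf_sigma_um",
                         "noise_sd", "outer_radius")]), seed = seeds[3]))
  morpho <- stage("morphometry",
                  analyze_microct(ct, roi_sector = cfg$ct$roi_sector,
                                  window_mm = cfg$ct$window_mm))
  cohort <- stage("cohort",
                  generate_cohort(default_cohort_spec(),
                                  n_fx = cfg$cohort$n_fx,
                                  n_nfx = cfg$cohort$n_nfx,
                                  n_vertebral = cfg$cohort$n_vertebral,
                                  n_other = cfg$cohort$n_other,
                                  missing_spine_frac = cfg$cohort$missing_spine_frac,
                                  seed = seeds[4]))
  disc <- lapply(cfg$discrimination$endpoints, function(ep)
    stage(paste0("discrimination_", ep),
          discriminate_fractures(cohort, endpoint = ep,
                                 features = cfg$discrimination$features,
                                 ncomp = cfg$discrimination$ncomp,
                                 seed = seeds[5])))
  names(disc) <- cfg$discrimination$endpoints
  disc_tab <- do.call(rbind, lapply(names(disc), function(ep) {
    d <- disc[[ep]]
    data.frame(endpoint = ep, sensitivity = d$roc$sensitivity,
               specificity = d$roc$specificity, auc = d$roc$auc,
               se = d$roc$se, accuracy = d$roc$accuracy,
               or = d$or$or, ci_low = d$or$ci[1], ci_high = d$or$ci[2],
               variables = paste(d$variables, collapse = ";"))
  }))
  structure(list(
    provenance = list(version = CONTAINER_VERSION,
                      package = as.character(utils::packageVersion("cortbs")),
                      seed = cfg$seed, hash = config_hash(cfg),
                      config = cfg),
    population = pop, rf_truth = rf$truth[c("alpha0", "alphaf", "snr_db")],
    compound = img, surface = surf, nds = nds, quality = qs,
    attenuation = att, bsc = bsc, distribution = dist,
    volume = ct, morphometry = morpho,
    cohort = cohort, discrimination = disc,
    summary = list(discrimination = disc_tab,
                   quality = qs$fraction,
                   ct_alpha0 = if (!is.null(att)) att$ct_alpha0 else NA,
                   ct_alphaf = if (!is.null(att)) att$ct_alphaf else NA)),
    class = "result_bundle")
}

#' Write a result bundle to a directory container
#'
#' Plain-text container: JSON for scalars/descriptors/provenance, CSV for
#' tables and spectra, multi-page TIFF (+ JSON sidecar with voxel size and
#' calibration) for the volume. Rewriting the same bundle produces
#' byte-identical files.
#'
#' @param bundle A [run_pipeline()] `result_bundle`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_container <- function(bundle, path) {
  stopifnot(inherits(bundle, "result_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(path, f), auto_unbox = TRUE, digits = NA, force = TRUE,
    pretty = TRUE, na = "null")
  wc <- function(d, f) utils::write.csv(d, file.path(path, f),
                                        row.names = FALSE)
  wj(bundle$provenance, "manifest.json")
  wc(as.data.frame(bundle$cohort), "cohort.csv")
  nds <- bundle$nds
  nds_tab <- data.frame(depth = rep(nds$depth, length(nds$freq)),
                        frequency = rep(nds$freq, each = length(nds$depth)),
                        nds_db = as.vector(nds$values),
                        counts = rep(nds$counts, length(nds$freq)))
  wc(nds_tab, "nds.csv")
  if (!is.null(bundle$attenuation)) {
    wc(bundle$attenuation$alpha_f, "alpha.csv")
    wc(bundle$bsc$spectrum, "bsc.csv")
    wc(data.frame(diameter = bundle$distribution$d_grid,
                  density = bundle$distribution$density), "pore_dist.csv")
    wj(list(ct_alpha0 = bundle$attenuation$ct_alpha0,
            ct_alphaf = bundle$attenuation$ct_alphaf,
            quality = bundle$quality$fraction,
            quality_pass = bundle$quality$pass,
            descriptors = bundle$distribution$descriptors),
       "spectral_summary.json")
  } else {
    wj(list(quality = bundle$quality$fraction, quality_pass = FALSE,
            excluded = "quality score below threshold"),
       "spectral_summary.json")
  }
  wj(bundle$morphometry$regions, "morphometry.json")
  wc(bundle$summary$discrimination, "discrimination.csv")
  # compound envelope image (mid tilt) for audit of the imaging chain
  env <- bundle$compound$envelope[, , ceiling(dim(bundle$compound$envelope)[3] / 2)]
  wc(data.frame(depth = rep(bundle$compound$depth_mm, ncol(env)),
                lateral = rep(bundle$compound$lateral_mm, each = nrow(env)),
                envelope = as.vector(env)), "compound_mid_tilt.csv")
  vol <- bundle$volume
  lo <- min(vol$data); hi <- max(vol$data)
  rngv <- max(hi - lo, 1e-12)
  pages <- lapply(seq_len(dim(vol$data)[3]), function(s)
    (vol$data[, , s] - lo) / rngv)
  tiff::writeTIFF(pages, file.path(path, "volume.tif"),
                  bits.per.sample = 16L, compression = "none")
  wj(list(voxel_um = vol$voxel_um, scale_min = lo, scale_range = rngv,
          matrix_vbmd = vol$calibration$matrix_vbmd,
          n_slices = dim(vol$data)[3]), "volume.json")
  invisible(path)
}

#' Read a result-bundle container
#'
#' Restores the tabular and volume content written by [write_container()].
#' An unrecognized version tag or an unreadable file is an explicit error;
#' no partial results are returned.
#'
#' @param path Container directory.
#' @return List with `provenance`, `cohort`, `nds`, `alpha`, `bsc`,
#'   `pore_dist`, `spectral_summary`, `morphometry`, `discrimination`,
#'   `volume` (array + metadata).
#' @export
read_container <- function(path) {
  man_f <- file.path(path, "manifest.json")
  if (!file.exists(man_f)) fail("not a container: %s missing", man_f)
  man <- tryCatch(jsonlite::read_json(man_f, simplifyVector = TRUE),
                  error = function(e) fail("corrupted manifest: %s",
                                           conditionMessage(e)))
  if (!identical(man$version, CONTAINER_VERSION))
    fail("container version '%s' not recognized (expected '%s')",
         man$version %||% "<none>", CONTAINER_VERSION)
  rj <- function(f) tryCatch(
    jsonlite::read_json(file.path(path, f), simplifyVector = TRUE),
    error = function(e) fail("corrupted %s: %s", f, conditionMessage(e)))
  rc <- function(f) tryCatch(
    utils::read.csv(file.path(path, f)),
    error = function(e) fail("corrupted %s: %s", f, conditionMessage(e)))
  vol_meta <- rj("volume.json")
  pages <- tryCatch(tiff::readTIFF(file.path(path, "volume.tif"),
                                   all = TRUE),
                    error = function(e) fail("corrupted volume.tif: %s",
                                             conditionMessage(e)))
  vol <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (s in seq_along(pages))
    vol[, , s] <- pages[[s]] * vol_meta$scale_range + vol_meta$scale_min
  out <- list(provenance = man,
              cohort = rc("cohort.csv"),
              nds = rc("nds.csv"),
              spectral_summary = rj("spectral_summary.json"),
              morphometry = rj("morphometry.json"),
              discrimination = rc("discrimination.csv"),
              volume = list(data = vol, voxel_um = vol_meta$voxel_um,
                            matrix_vbmd = vol_meta$matrix_vbmd))
  if (file.exists(file.path(path, "alpha.csv"))) {
    out$alpha <- rc("alpha.csv")
    out$bsc <- rc("bsc.csv")
    out$pore_dist <- rc("pore_dist.csv")
  }
  out
}
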