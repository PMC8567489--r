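#' Default cohort specification
#'
#' Per-group means and SDs for a postmenopausal cohort with (Fx) and
#' without (nFx) fragility fractures, matching the group statistics of the
#' clinical study the package emulates: anthropometrics, DXA aBMD and
#' T-scores, CortBS attenuation and pore-size-distribution descriptors,
#' and site-matched HR-pQCT custom parameters. Variables are grouped into
#' modality blocks; within-block correlation defaults to 0.3, across
#' blocks to 0.
#'
#' @param within_cor Within-modality correlation (default 0.3).
#' @return Object of class `cohort_spec`: data frame `variables` with
#'   columns name, block, mean_fx, sd_fx, mean_nfx, sd_nfx, and the
#'   correlation setting.
#' @export
default_cohort_spec <- function(within_cor = 0.3) {
  v <- rbind(
    data.frame(name = "Age",    block = "anthro", mean_fx = 69.2,  sd_fx = 7.5,  mean_nfx = 70.2,  sd_nfx = 6.3),
    data.frame(name = "Height", block = "anthro", mean_fx = 165.0, sd_fx = 8.1,  mean_nfx = 163.1, sd_nfx = 7.2),
    data.frame(name = "Weight", block = "anthro", mean_fx = 62.4,  sd_fx = 9.1,  mean_nfx = 61.0,  sd_nfx = 6.7),
    data.frame(name = "aBMD.Femur.Total", block = "dxa", mean_fx = 0.786, sd_fx = 0.072, mean_nfx = 0.808, sd_nfx = 0.076),
    data.frame(name = "aBMD.Femur.Neck",  block = "dxa", mean_fx = 0.793, sd_fx = 0.081, mean_nfx = 0.805, sd_nfx = 0.072),
    data.frame(name = "aBMD.Spine",       block = "dxa", mean_fx = 0.904, sd_fx = 0.130, mean_nfx = 0.950, sd_nfx = 0.110),
    data.frame(name = "T.score.Femur",    block = "dxa", mean_fx = -1.93, sd_fx = 0.86,  mean_nfx = -1.83, sd_nfx = 0.55),
    data.frame(name = "T.score.Spine",    block = "dxa", mean_fx = -2.28, sd_fx = 1.04,  mean_nfx = -1.90, sd_nfx = 0.90),
    data.frame(name = "Ct.alpha0",  block = "cortbs", mean_fx = 2.34, sd_fx = 0.40, mean_nfx = 1.96, sd_nfx = 0.48),
    data.frame(name = "Ct.alphaf",  block = "cortbs", mean_fx = 0.11, sd_fx = 0.06, mean_nfx = 0.16, sd_nfx = 0.06),
    data.frame(name = "Ct.Po.Dm.D_Peak",     block = "cortbs", mean_fx = 38.6, sd_fx = 5.6, mean_nfx = 36.6, sd_nfx = 7.1),
    data.frame(name = "Ct.Po.Dm.D_Q10",      block = "cortbs", mean_fx = 29.9, sd_fx = 4.7, mean_nfx = 28.8, sd_nfx = 5.8),
    data.frame(name = "Ct.Po.Dm.D_Q90",      block = "cortbs", mean_fx = 48.7, sd_fx = 7.1, mean_nfx = 45.3, sd_nfx = 8.8),
    data.frame(name = "Ct.Po.Dm.D_FWHM",     block = "cortbs", mean_fx = 16.5, sd_fx = 3.5, mean_nfx = 14.9, sd_nfx = 2.9),
    data.frame(name = "Ct.Po.Dm.D_FWHM.min", block = "cortbs", mean_fx = 31.1, sd_fx = 5.0, mean_nfx = 29.5, sd_nfx = 5.8),
    data.frame(name = "Ct.Po.Dm.D_FWHM.max", block = "cortbs", mean_fx = 47.6, sd_fx = 6.8, mean_nfx = 44.4, sd_nfx = 8.6),
    data.frame(name = "Ct.Th.ROI",        block = "hrpqct", mean_fx = 2.7,  sd_fx = 0.8,  mean_nfx = 2.7,  sd_nfx = 0.6),
    data.frame(name = "Ct.Po.BH.ROI",     block = "hrpqct", mean_fx = 5.4,  sd_fx = 2.3,  mean_nfx = 4.5,  sd_nfx = 2.2),
    data.frame(name = "Ct.Po.D_SD.ROI",   block = "hrpqct", mean_fx = 6.0,  sd_fx = 1.2,  mean_nfx = 5.4,  sd_nfx = 1.1),
    data.frame(name = "Ct.Po.D_VAR.ROI",  block = "hrpqct", mean_fx = 37.5, sd_fx = 16.2, mean_nfx = 30.1, sd_nfx = 13.2),
    data.frame(name = "Ct.Po.D_skewness.Full", block = "hrpqct", mean_fx = 0.98, sd_fx = 0.37, mean_nfx = 1.35, sd_nfx = 0.51),
    data.frame(name = "Ct.Po.D_kurtosis.Full", block = "hrpqct", mean_fx = 5.1,  sd_fx = 1.5,  mean_nfx = 7.3,  sd_nfx = 3.4),
    data.frame(name = "Ct.Po.Dm.D_Mean.ROI", block = "hrpqct", mean_fx = 128, sd_fx = 20, mean_nfx = 120, sd_nfx = 15),
    data.frame(name = "Ct.Po.Dm.D_SD.ROI",   block = "hrpqct", mean_fx = 83,  sd_fx = 28, mean_nfx = 74,  sd_nfx = 23),
    data.frame(name = "Ct.Po.Dm.D_Q90.ROI",  block = "hrpqct", mean_fx = 230, sd_fx = 54, mean_nfx = 205, sd_nfx = 35)
  )
  structure(list(variables = v, within_cor = within_cor, across_cor = 0),
            class = "cohort_spec")
}

#' Generate a synthetic cohort table
#'
#' Draws one row per subject from per-group multivariate normal
#' distributions with block-diagonal correlation (within-modality
#' correlation as configured, zero across modalities). BMI is derived from
#' height and weight (so it is always consistent with them); fracture
#' subtype flags (vertebral/other) are assigned to match the configured
#' counts, with the overlap implied by `n_vertebral + n_other - n_fx`
#' subjects carrying both; a configurable fraction of spine T-scores (and
#' spine aBMD) is set missing, emulating degenerative lumbar changes that
#' preclude a valid spine scan. Missing values are flagged as NA and never
#' imputed.
#'
#' @param spec A [default_cohort_spec()] (or modified copy).
#' @param n_fx,n_nfx Group sizes (defaults 29/26).
#' @param n_vertebral,n_other Fracture-subtype counts within Fx
#'   (defaults 18/21).
#' @param missing_spine_frac Fraction of subjects with missing spine
#'   T-score (default 0.15).
#' @param seed Integer seed.
#' @return A `data.frame` of class `cohort_table` with columns `id`,
#'   `group` ("Fx"/"nFx"), `vertebral`, `other`, all spec variables, and
#'   `BMI`.
#' @export
generate_cohort <- function(spec = default_cohort_spec(), n_fx = 29,
                            n_nfx = 26, n_vertebral = 18, n_other = 21,
                            missing_spine_frac = 0.15, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  v <- spec$variables
  p <- nrow(v)
  if (n_vertebral + n_other < n_fx)
    fail("subtype counts (%d + %d) cannot cover all %d fractured subjects",
         n_vertebral, n_other, n_fx)
  if (n_vertebral > n_fx || n_other > n_fx)
    fail("subtype count exceeds the fractured group size")
  C <- matrix(0, p, p, dimnames = list(v$name, v$name))
  for (b in unique(v$block)) {
    i <- which(v$block == b)
    C[i, i] <- spec$within_cor
  }
  diag(C) <- 1
  ch <- tryCatch(chol(C), error = function(e)
    fail("correlation matrix not positive definite in block structure (within_cor = %g)",
         spec$within_cor))
  draw <- function(n, mu, sd) {
    z <- matrix(stats::rnorm(n * p), n, p) %*% ch
    sweep(sweep(z, 2, sd, "*"), 2, mu, "+")
  }
  with_seed(seed, {
    fx <- draw(n_fx, v$mean_fx, v$sd_fx)
    nfx <- draw(n_nfx, v$mean_nfx, v$sd_nfx)
    tab <- as.data.frame(rbind(fx, nfx))
    names(tab) <- v$name
    tab <- cbind(id = sprintf("S%03d", seq_len(n_fx + n_nfx)),
                 group = rep(c("Fx", "nFx"), c(n_fx, n_nfx)), tab,
                 stringsAsFactors = FALSE)
    tab$BMI <- tab$Weight / (tab$Height / 100)^2
    # subtype flags: n_both subjects carry both fracture types
    n_both <- n_vertebral + n_other - n_fx
    idx <- sample.int(n_fx)
    vert_ids <- idx[seq_len(n_vertebral)]
    other_ids <- c(idx[seq_len(n_both)],
                   idx[setdiff(seq_len(n_fx), seq_len(n_vertebral))])
    tab$vertebral <- FALSE; tab$other <- FALSE
    tab$vertebral[vert_ids] <- TRUE
    tab$other[other_ids] <- TRUE
    n_miss <- round(missing_spine_frac * nrow(tab))
    if (n_miss > 0) {
      miss <- sample.int(nrow(tab), n_miss)
      tab$T.score.Spine[miss] <- NA_real_
      tab$aBMD.Spine[miss] <- NA_real_
    }
    class(tab) <- c("cohort_table", "data.frame")
    tab
  })
}

#' Modality feature blocks of a cohort table
#'
#' @param spec A `cohort_spec`.
#' @param block One of "cortbs", "hrpqct", "dxa", "anthro".
#' @return Character vector of variable names.
#' @export
cohort_block <- function(spec, block) {
  spec$variables$name[spec$variables$block == block]
}
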