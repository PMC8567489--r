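#' ROC metrics and confusion matrix at the Youden-optimal threshold
#'
#' AUC by the rank (Mann-Whitney) formula with midrank tie handling; its
#' standard error by the Hanley-McNeil formula with
#' `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`. The operating point maximizes
#' Youden's J = sensitivity + specificity - 1 over all thresholds
#' (subjects with score >= threshold are called positive); ties in J are
#' broken toward the higher specificity.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Logical/0-1/factor labels; `positive` names the positive
#'   level for factors.
#' @param positive Positive level when `labels` is a factor/character.
#' @return Object of class `roc_metrics`: `auc`, `se`, `sensitivity`,
#'   `specificity`, `accuracy`, `threshold`, and `confusion` (list TP,
#'   FN, TN, FP).
#' @export
roc_metrics <- function(scores, labels, positive = NULL) {
  if (is.factor(labels) || is.character(labels)) {
    if (is.null(positive)) positive <- sort(unique(as.character(labels)))[1]
    labels <- as.character(labels) == positive
  }
  labels <- as.logical(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) fail("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  thr <- c(sort(unique(scores)), Inf)
  best <- NULL
  for (t in thr) {
    pos <- scores >= t
    tp <- sum(pos & labels); fn <- n1 - tp
    fp <- sum(pos & !labels); tn <- n0 - fp
    sens <- tp / n1; spec <- tn / n0
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec))
      best <- list(j = j, sens = sens, spec = spec, t = t,
                   cm = list(TP = tp, FN = fn, TN = tn, FP = fp))
  }
  structure(list(auc = auc, se = se,
                 sensitivity = best$sens, specificity = best$spec,
                 accuracy = (best$cm$TP + best$cm$TN) / (n1 + n0),
                 threshold = best$t, confusion = best$cm,
                 n_pos = n1, n_neg = n0),
            class = "roc_metrics")
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = (TP * TN) / (FN * FP)` from a confusion matrix, with the
#' Haldane-Anscombe +0.5 correction applied to every cell when any cell
#' is zero, and the Woolf log-normal 95% CI.
#'
#' @param cm List or vector with TP, FN, TN, FP.
#' @param conf_level Confidence level (default 0.95).
#' @return List: `or`, `ci` (length 2), `corrected`.
#' @export
odds_ratio <- function(cm, conf_level = 0.95) {
  cm <- as.list(cm)
  cells <- c(cm$TP, cm$FN, cm$TN, cm$FP)
  if (any(cells < 0)) fail("negative cell counts")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[3]) / (cells[2] * cells[4])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_log <- sqrt(sum(1 / cells))
  list(or = or,
       ci = exp(log(or) + c(-1, 1) * z * se_log),
       corrected = corrected)
}

#' Compare two AUCs (Hanley-McNeil z-test)
#'
#' \deqn{z = (A_1 - A_2) / \sqrt{SE_1^2 + SE_2^2 - 2 r SE_1 SE_2}}
#' with two-sided normal p-value; `r` is the correlation induced by
#' evaluating both models on the same subjects (0 for independent
#' samples).
#'
#' @param roc1,roc2 [roc_metrics()] results.
#' @param r Correlation between the two AUC estimates, in `[0, 1]`.
#' @return List: `z`, `p`.
#' @export
compare_auc <- function(roc1, roc2, r = 0) {
  stopifnot(r >= 0, r <= 1)
  den <- sqrt(roc1$se^2 + roc2$se^2 - 2 * r * roc1$se * roc2$se)
  if (!is.finite(den) || den == 0) fail("zero denominator in AUC comparison")
  z <- (roc1$auc - roc2$auc) / den
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Reconstruct an integer confusion matrix from printed test metrics
#'
#' Given a reported sensitivity and specificity (printed to two decimals)
#' together with the group sizes, recover the integer cell counts by
#' rounding, and recompute the implied accuracy and odds ratio. Used for
#' checking the internal consistency of published discrimination tables.
#'
#' @param sensitivity,specificity Reported values.
#' @param n_pos,n_neg Group sizes.
#' @return List: `confusion` (TP, FN, TN, FP), `accuracy`, `or` (list from
#'   [odds_ratio()]), and the achieved sensitivity/specificity.
#' @export
reconstruct_confusion <- function(sensitivity, specificity, n_pos, n_neg) {
  tp <- round(sensitivity * n_pos)
  tn <- round(specificity * n_neg)
  cm <- list(TP = tp, FN = n_pos - tp, TN = tn, FP = n_neg - tn)
  list(confusion = cm,
       accuracy = (tp + tn) / (n_pos + n_neg),
       or = odds_ratio(cm),
       sensitivity = tp / n_pos,
       specificity = tn / n_neg)
}

#' Binormal AUC implied by two group means and SDs
#'
#' For normally distributed scores in two groups, the AUC of the ideal
#' single-feature discriminator is
#' \eqn{\Phi(|\mu_1 - \mu_2| / \sqrt{\sigma_1^2 + \sigma_2^2})}.
#'
#' @param mean1,sd1,mean2,sd2 Group summary statistics.
#' @return AUC in `[0.5, 1]`.
#' @export
binormal_auc <- function(mean1, sd1, mean2, sd2) {
  stats::pnorm(abs(mean1 - mean2) / sqrt(sd1^2 + sd2^2))
}

#' PLS-LOOCV fracture discrimination on a cohort table
#'
#' Builds the requested feature block (optionally with anthropometrics and
#' age), performs listwise deletion, optionally runs SPA variable
#' selection, computes leave-one-out cross-validated PLS-DA scores, and
#' summarizes discrimination with ROC metrics, the Youden-point confusion
#' matrix, and the odds ratio.
#'
#' @param cohort A [generate_cohort()] table.
#' @param endpoint "vertebral", "other", or "all".
#' @param features Character vector of feature columns, or one of
#'   "cortbs", "hrpqct", "dxa" to use a modality block of
#'   [default_cohort_spec()].
#' @param anthropometric Add height, weight, BMI and age.
#' @param select Run [spa_select()] first (default FALSE).
#' @param ncomp PLS components.
#' @param n_mc Monte Carlo rounds for SPA when `select = TRUE`.
#' @param seed Seed (SPA and fold assignment).
#' @return Object of class `discrimination_result`: per-subject scores,
#'   labels, selected variables, `roc` (a `roc_metrics`), `or`, endpoint,
#'   and the subject ids used.
#' @export
discriminate_fractures <- function(cohort, endpoint = c("all", "vertebral",
                                                        "other"),
                                   features = "cortbs",
                                   anthropometric = FALSE,
                                   select = FALSE, ncomp = 3,
                                   n_mc = 1000, seed = NULL) {
  endpoint <- match.arg(endpoint)
  if (length(features) == 1 &&
      features %in% c("cortbs", "hrpqct", "dxa"))
    features <- cohort_block(default_cohort_spec(), features)
  if (anthropometric)
    features <- c(features, "Height", "Weight", "BMI", "Age")
  miss <- setdiff(features, names(cohort))
  if (length(miss)) fail("cohort lacks columns: %s", paste(miss, collapse = ", "))
  lab <- switch(endpoint,
                all = cohort$group == "Fx",
                vertebral = cohort$group == "Fx" & cohort$vertebral,
                other = cohort$group == "Fx" & cohort$other)
  # listwise deletion per endpoint model
  keep <- switch(endpoint,
                 all = rep(TRUE, nrow(cohort)),
                 vertebral = cohort$group == "nFx" | cohort$vertebral,
                 other = cohort$group == "nFx" | cohort$other)
  X <- as.matrix(cohort[, features, drop = FALSE])
  keep <- keep & stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  y <- ifelse(lab[keep], 1, -1)
  seeds <- child_seeds(seed %||% 0L, 2)
  vars <- colnames(X)
  if (select) {
    vars <- spa_select(X, y, n_mc = n_mc, ncomp = ncomp, seed = seeds[1])
    if (length(vars) < 2) vars <- colnames(X)
  }
  cv <- cross_validated_pls(X[, vars, drop = FALSE], y, ncomp = ncomp,
                            scheme = "loocv", seed = seeds[2])
  roc <- roc_metrics(cv$predictions, y > 0)
  structure(list(scores = cv$predictions, labels = y > 0,
                 variables = vars, roc = roc,
                 or = odds_ratio(roc$confusion),
                 endpoint = endpoint,
                 ids = cohort$id[keep]),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("PLS-LOOCV discrimination (%s): AUC %.2f (SE %.3f), sens %.2f, spec %.2f, acc %.2f, OR %.1f\n",
              x$endpoint, x$roc$auc, x$roc$se, x$roc$sensitivity,
              x$roc$specificity, x$roc$accuracy, x$or$or))
  cat("  variables:", paste(x$variables, collapse = ", "), "\n")
  invisible(x)
}
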