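test_that("perfect separation gives AUC 1 and a perfect operating point", {
  r <- roc_metrics(c(1, 2, 3, 11, 12, 13), c(F, F, F, T, T, T))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$accuracy, 1)
})

test_that("AUC equals the brute-force pairwise concordance count", {
  set.seed(21)
  scores <- c(2.4, 1.1, 3.0, 0.7, 2.9, 1.8, 2.2, 0.5, 1.5, 2.6, 0.9, 1.2)
  labels <- c(T, F, T, F, T, F, T, F, F, T, F, T)
  r <- roc_metrics(scores, labels)
  pos <- scores[labels]; neg <- scores[!labels]
  u <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
  expect_equal(r$auc, u / (length(pos) * length(neg)), tolerance = 1e-12)
})

test_that("AUC and SE agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  scores <- rnorm(40) + rep(c(0.8, 0), c(18, 22))
  labels <- rep(c(TRUE, FALSE), c(18, 22))
  r <- roc_metrics(scores, labels)
  ref <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(23)
  scores <- rnorm(30)
  labels <- rep(c(TRUE, FALSE), 15)
  a1 <- roc_metrics(scores, labels)$auc
  a2 <- roc_metrics(exp(2 * scores) + 5, labels)$auc
  expect_equal(a1, a2)
})

test_that("negating scores and swapping labels mirrors the AUC", {
  set.seed(24)
  scores <- rnorm(25)
  labels <- rep(c(TRUE, FALSE), c(12, 13))
  a <- roc_metrics(scores, labels)$auc
  a_neg <- roc_metrics(-scores, !labels)$auc
  expect_equal(a, a_neg, tolerance = 1e-12)
})

test_that("Hanley-McNeil SE follows the closed form", {
  set.seed(25)
  scores <- rnorm(30) + rep(c(1, 0), 15)
  labels <- rep(c(TRUE, FALSE), 15)
  r <- roc_metrics(scores, labels)
  a <- r$auc; n1 <- 15; n0 <- 15
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
               (n1 * n0))
  expect_equal(r$se, se, tolerance = 1e-12)
})

test_that("single-class labels are refused", {
  expect_error(roc_metrics(1:5, rep(TRUE, 5)), "both classes")
})

test_that("odds ratios reproduce the worked confusion-matrix examples", {
  expect_equal(odds_ratio(list(TP = 7, FN = 7, TN = 34, FP = 2))$or, 17.0)
  expect_equal(odds_ratio(list(TP = 6, FN = 8, TN = 33, FP = 3))$or, 8.25)
  sym <- odds_ratio(list(TP = 5, FN = 5, TN = 5, FP = 5))
  expect_equal(sym$or, 1)
  expect_lt(sym$ci[1], 1); expect_gt(sym$ci[2], 1)
})

test_that("zero cells engage the Haldane-Anscombe correction", {
  r <- odds_ratio(list(TP = 10, FN = 0, TN = 12, FP = 3))
  expect_true(r$corrected)
  expect_true(is.finite(r$or) && is.finite(r$ci[2]))
  expect_error(odds_ratio(list(TP = -1, FN = 2, TN = 3, FP = 4)), "negative")
})

test_that("identical ROCs compare as z = 0, p = 1", {
  set.seed(26)
  scores <- rnorm(30)
  labels <- rep(c(TRUE, FALSE), 15)
  r <- roc_metrics(scores, labels)
  cmp <- compare_auc(r, r, r = 0.5)
  expect_equal(cmp$z, 0)
  expect_equal(cmp$p, 1)
  r0 <- r; r0$se <- 0
  expect_error(compare_auc(r0, r0, r = 0), "denominator")
})

test_that("the AUC-difference sign matches a permutation test's direction", {
  # two models scored on the same subjects: model A informative, model B
  # noise; compare_auc should point the same way as a label permutation
  set.seed(27)
  n <- 40
  labels <- rep(c(TRUE, FALSE), 20)
  sA <- rnorm(n) + labels * 1.2
  sB <- rnorm(n)
  rA <- roc_metrics(sA, labels); rB <- roc_metrics(sB, labels)
  cmp <- compare_auc(rA, rB, r = 0.3)
  perm <- replicate(200, {
    lp <- sample(labels)
    roc_metrics(sA, lp)$auc - roc_metrics(sB, lp)$auc
  })
  obs <- rA$auc - rB$auc
  expect_gt(cmp$z, 0)
  expect_gt(obs, quantile(perm, 0.95))
})

test_that("discrimination on a default cohort returns a coherent result", {
  cohort <- generate_cohort(seed = 31)
  d <- discriminate_fractures(cohort, endpoint = "vertebral",
                              features = "cortbs", seed = 32)
  expect_equal(length(d$scores), length(d$labels))
  expect_equal(sum(d$labels), 18)
  expect_true(d$roc$auc >= 0 && d$roc$auc <= 1)
  cm <- d$roc$confusion
  expect_equal(cm$TP + cm$FN, sum(d$labels))
  expect_equal(cm$TN + cm$FP, sum(!d$labels))
  expect_equal(d$roc$accuracy, (cm$TP + cm$TN) / length(d$labels))
})
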