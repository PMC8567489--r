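test_that("large-sample group means converge to the configured values", {
  tab <- generate_cohort(n_fx = 1e4, n_nfx = 1e4, n_vertebral = 6000,
                         n_other = 6000, seed = 1)
  fx <- tab[tab$group == "Fx", ]
  # 3 standard errors of the mean at n = 1e4
  expect_lt(abs(mean(fx$Ct.alpha0) - 2.34), 3 * 0.40 / 100)
  expect_lt(abs(mean(fx$Ct.alphaf) - 0.11), 3 * 0.06 / 100)
  expect_lt(abs(sd(fx$Ct.alpha0) - 0.40), 0.02)
  nfx <- tab[tab$group == "nFx", ]
  expect_lt(abs(mean(nfx$Ct.alpha0) - 1.96), 3 * 0.48 / 100)
  expect_lt(abs(mean(nfx$T.score.Spine, na.rm = TRUE) - (-1.90)),
            3 * 0.90 / 95)
})

test_that("within-block correlation is close to the configured 0.3", {
  tab <- generate_cohort(n_fx = 8000, n_nfx = 100, n_vertebral = 5000,
                         n_other = 5000, seed = 2)
  fx <- tab[tab$group == "Fx", ]
  r_within <- cor(fx$Ct.alpha0, fx$Ct.alphaf)
  r_across <- cor(fx$Ct.alpha0, fx$Age)
  expect_lt(abs(r_within - 0.3), 0.05)
  expect_lt(abs(r_across), 0.05)
})

test_that("default cohort matches the study layout and invariants", {
  tab <- generate_cohort(seed = 3)
  expect_equal(nrow(tab), 55)
  expect_equal(sum(tab$group == "Fx"), 29)
  expect_equal(sum(tab$vertebral), 18)
  expect_equal(sum(tab$other), 21)
  # every fractured subject has at least one subtype; controls have none
  fx <- tab$group == "Fx"
  expect_true(all(tab$vertebral[fx] | tab$other[fx]))
  expect_true(all(!tab$vertebral[!fx] & !tab$other[!fx]))
  # BMI consistent with height and weight
  expect_equal(tab$BMI, tab$Weight / (tab$Height / 100)^2, tolerance = 1e-12)
  # ~15% missing spine T-scores, flagged as NA
  expect_equal(sum(is.na(tab$T.score.Spine)), round(0.15 * 55))
  expect_identical(generate_cohort(seed = 3), tab)
})

test_that("an impossible correlation block is rejected by name", {
  spec <- default_cohort_spec(within_cor = -0.5)
  expect_error(generate_cohort(spec, seed = 1), "positive definite")
})

test_that("impossible subtype counts are rejected", {
  expect_error(generate_cohort(n_fx = 29, n_nfx = 26, n_vertebral = 5,
                               n_other = 5, seed = 1), "subtype")
})
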