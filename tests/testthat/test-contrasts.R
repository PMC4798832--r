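fit_hatch <- function(seed = 1, reps = 2) {
  rec <- quick_records(seed = seed, reps = reps)
  ncii_lmm(hatch_dd ~ analysis_group + (1 | sire_id) + (1 | dam_id) +
             (1 | sire_id:dam_id), rec)
}

test_that("seven analysis groups yield 21 ordered contrasts", {
  fit <- fit_hatch(seed = 4)
  ct <- pairwise_contrasts(fit, nsim = 2e4, seed = 2)
  expect_equal(nrow(ct), choose(7, 2))
  levs <- levels(factor(fit$frame$analysis_group))
  ia <- match(ct$group_a, levs)
  ib <- match(ct$group_b, levs)
  expect_true(all(ia < ib))  # pairs in factor order, no duplicates
  expect_true(all(ct$p_adjusted >= ct$p_raw - 1e-12))
  expect_true(all(ct$p_adjusted <= 1 & ct$p_raw >= 0))
})

test_that("a single contrast needs no adjustment", {
  rec <- quick_records(seed = 5)
  sub <- rec[rec$analysis_group %in% c("control", "AgNO3_high"), ]
  fit <- ncii_lmm(hatch_dd ~ analysis_group + (1 | sire_id) +
                    (1 | dam_id) + (1 | sire_id:dam_id), sub)
  ct <- pairwise_contrasts(fit, nsim = 2e5, seed = 3)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$p_adjusted, ct$p_raw, tolerance = 0.02)
})

test_that("independent contrasts reproduce the closed-form adjustment", {
  # two independent z's with raw two-sided p = 0.05:
  # adjusted p = 1 - 0.95^2 = 0.0975
  z <- c(qnorm(0.975), 0.2)
  p <- ncii:::adjust_max_abs_z(z, diag(2), nsim = 4e5, seed = 9)
  expect_lt(abs(p[1] - (1 - 0.95^2)), 0.002)  # ~4 Monte Carlo SEs
})

test_that("adjusted p-values agree with the established single-step method", {
  skip_if_not_installed("multcomp")
  rec <- quick_records(seed = 7, reps = 3)
  rec <- rec[rec$analysis_group %in%
               c("control", "AgNO3_low", "AgNO3_high", "AgNP20_high"), ]
  rec$analysis_group <- factor(rec$analysis_group)
  fit <- ncii_lmm(hatch_dd ~ analysis_group + (1 | sire_id) +
                    (1 | dam_id) + (1 | sire_id:dam_id), rec)
  ct <- pairwise_contrasts(fit, nsim = 2e5, seed = 4)
  skip_if_not_installed("lme4")
  ref_fit <- lme4::lmer(hatch_dd ~ analysis_group + (1 | sire_id) +
                          (1 | dam_id) + (1 | sire_id:dam_id), rec)
  gh <- multcomp::glht(ref_fit,
                       linfct = multcomp::mcp(analysis_group = "Tukey"))
  ref_p <- summary(gh)$test$pvalues
  # match pairs: glht reports "b - a"; our rows are (a, b) with estimate a-b
  ours <- ct$p_adjusted
  expect_equal(length(ours), length(ref_p))
  expect_equal(sort(ours), sort(as.numeric(ref_p)), tolerance = 0.03)
})

test_that("contrast preconditions are enforced", {
  fit <- fit_hatch(seed = 4)
  expect_error(pairwise_contrasts(fit, factor = "absent"), "not in model")
  fit$converged <- FALSE
  expect_error(pairwise_contrasts(fit), "converge")
})
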