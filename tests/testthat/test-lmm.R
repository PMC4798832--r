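test_that("REML matches the closed form for balanced one-way data", {
  set.seed(42)
  a <- 30
  n <- 8
  g <- rep(sprintf("G%02d", seq_len(a)), each = n)
  y <- rnorm(a, 0, 2)[as.integer(factor(g))] + rnorm(a * n, 0, 1)
  d <- data.frame(y = y, g = g)
  fit <- ncii_lmm(y ~ 1 + (1 | g), d)
  gm <- tapply(y, g, mean)
  msb <- n * sum((gm - mean(y))^2) / (a - 1)
  msw <- sum((y - gm[g])^2) / (a * (n - 1))
  expect_equal(unname(fit$sigma2[["g"]]), (msb - msw) / n,
               tolerance = 1e-5)
  expect_equal(fit$sigma2_resid, msw, tolerance = 1e-5)
})

test_that("REML agrees with the expected-mean-squares oracle on balanced NC II data", {
  d <- sim_balanced_ncii(n_sires = 12, n_dams = 8, r = 6, seed = 10)
  orc <- anova_ncii(d, "y")
  expect_true(all(orc$sigma2 > 0))  # interior case
  fit <- ncii_lmm(ncii_formula, d)
  est <- c(fit$sigma2[["sire_id"]], fit$sigma2[["dam_id"]],
           fit$sigma2[["sire_id:dam_id"]], fit$sigma2_resid)
  expect_equal(est, unname(orc$sigma2), tolerance = 1e-4)
})

test_that("pure-noise data drive all variances to the boundary", {
  # a realization whose method-of-moments components are all negative, so
  # the constrained REML optimum sits exactly on the boundary
  d <- sim_balanced_ncii(s2 = c(sire = 0, dam = 0, sire_dam = 0,
                                resid = 1), seed = 2)
  expect_true(all(anova_ncii(d, "y")$sigma2[1:3] < 0))
  fit <- ncii_lmm(ncii_formula, d)
  expect_setequal(fit$boundary_terms, fit$random_labels)
  expect_true(all(fit$sigma2 == 0))
  expect_equal(unname(coef(fit)[1]), mean(d$y), tolerance = 1e-6)
})

test_that("fits agree with an independent REML implementation", {
  skip_if_not_installed("lme4")
  d <- sim_balanced_ncii(seed = 17)
  d$grp <- rep(c("a", "b"), length.out = nrow(d))
  for (reml in c(TRUE, FALSE)) {
    fit <- ncii_lmm(y ~ grp + (1 | sire_id) + (1 | dam_id) +
                      (1 | sire_id:dam_id), d, REML = reml)
    ref <- lme4::lmer(y ~ grp + (1 | sire_id) + (1 | dam_id) +
                        (1 | sire_id:dam_id), d, REML = reml)
    expect_equal(fit$loglik, as.numeric(stats::logLik(ref)),
                 tolerance = 1e-6)
    vc <- as.data.frame(lme4::VarCorr(ref))
    ref_s2 <- setNames(vc$vcov, vc$grp)
    expect_equal(unname(fit$sigma2[["sire_id"]]),
                 unname(ref_s2[["sire_id"]]), tolerance = 1e-3)
    expect_equal(fit$sigma2_resid, unname(ref_s2[["Residual"]]),
                 tolerance = 1e-3)
    expect_equal(unname(coef(fit)), unname(lme4::fixef(ref)),
                 tolerance = 1e-5)
  }
})

test_that("variance estimates are scale-equivariant and LRTs scale-invariant", {
  d <- sim_balanced_ncii(seed = 8)
  c_ <- 7.3
  d2 <- transform(d, y = y * c_)
  full <- ncii_lmm(ncii_formula, d)
  full2 <- ncii_lmm(ncii_formula, d2)
  expect_equal(unname(full2$sigma2), unname(full$sigma2) * c_^2,
               tolerance = 1e-4)
  expect_equal(full2$sigma2_resid, full$sigma2_resid * c_^2,
               tolerance = 1e-5)
  red <- ncii_lmm(y ~ 1 + (1 | sire_id) + (1 | dam_id), d)
  red2 <- ncii_lmm(y ~ 1 + (1 | sire_id) + (1 | dam_id), d2)
  expect_lt(abs(lrt(full, red)$chi2 - lrt(full2, red2)$chi2), 1e-6)
})

test_that("adding a random term never lowers the maximized likelihood", {
  for (seed in c(2, 5)) {
    d <- sim_balanced_ncii(seed = seed)
    small <- ncii_lmm(y ~ 1 + (1 | sire_id) + (1 | dam_id), d)
    big <- ncii_lmm(ncii_formula, d)
    expect_gte(big$loglik, small$loglik - 1e-6)
  }
})

test_that("the returned optimum beats a surrounding parameter grid", {
  d <- sim_balanced_ncii(n_sires = 6, n_dams = 4, r = 3, seed = 12)
  fit <- ncii_lmm(ncii_formula, d)
  pre <- ncii:::lmm_precompute(
    fit$y, fit$X, fit$Zs
  )
  at_opt <- ncii:::lmm_objective(
    exp(fit$optimizer$par), pre, REML = TRUE)
  grid <- expand.grid(g1 = exp(seq(-6, 2, length.out = 7)),
                      g2 = exp(seq(-6, 2, length.out = 7)),
                      g3 = exp(seq(-6, 2, length.out = 7)))
  vals <- apply(grid, 1, function(g) {
    ncii:::lmm_objective(as.numeric(g), pre, REML = TRUE)
  })
  expect_lte(at_opt, min(vals) + 1e-6)
})

test_that("degenerate designs raise clear errors", {
  d <- sim_balanced_ncii(seed = 1)
  d$dup <- as.numeric(factor(d$sire_id))
  d$dup2 <- d$dup * 2
  expect_error(ncii_lmm(y ~ dup + dup2 + (1 | sire_id), d), "collinear")
  d1 <- d[d$dam_id == "D01", ]
  expect_error(ncii_lmm(y ~ 1 + (1 | dam_id), d1), "fewer than 2 levels")
  expect_error(ncii_lmm(y ~ 1 + (1 | sire_id) + (1 | sire_id), d),
               "duplicate random terms")
  expect_error(ncii_lmm(y ~ 1 + (sire_id | dam_id), d),
               "random intercept")
})
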