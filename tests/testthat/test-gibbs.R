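test_that("chains are exactly reproducible given the seed", {
  d <- sim_balanced_ncii(n_sires = 6, n_dams = 3, r = 3, seed = 2)
  ch1 <- ncii_gibbs(ncii_formula, d, n_iter = 600, burn_in = 100,
                    thin = 5, seed = 42)
  ch2 <- ncii_gibbs(ncii_formula, d, n_iter = 600, burn_in = 100,
                    thin = 5, seed = 42)
  expect_identical(ch1$draws, ch2$draws)
  ch3 <- ncii_gibbs(ncii_formula, d, n_iter = 600, burn_in = 100,
                    thin = 5, seed = 43)
  expect_false(identical(ch1$draws, ch3$draws))
  expect_equal(nrow(ch1$draws), floor((600 - 100) / 5))
  expect_true(all(ch1$draws[, c("sire_id", "dam_id", "residual")] > 0))
})

test_that("the residual-variance posterior matches its conjugate closed form", {
  # no random terms, flat prior on the mean: sigma2_e | y is
  # inverse-gamma((nu + n - p)/2, (nu V + RSS)/2)
  set.seed(8)
  n <- 60
  d <- data.frame(y = rnorm(n, 5, 2))
  nu <- 0.002
  V <- 1
  ch <- ncii_gibbs(y ~ 1, d, prior = c(nu = nu, V = V),
                   n_iter = 22000, burn_in = 2000, thin = 2, seed = 31)
  draws <- ch$draws[, "residual"]
  rss <- sum((d$y - mean(d$y))^2)
  shape <- (nu + n - 1) / 2
  scale <- (nu * V + rss) / 2
  an_mean <- scale / (shape - 1)
  mcse <- sd(draws) / sqrt(length(draws) / 2)  # allow some autocorrelation
  expect_lt(abs(mean(draws) - an_mean), 4 * mcse)
  # Kolmogorov-Smirnov distance against the analytic CDF
  cdf <- function(x) pgamma(1 / x, shape = shape, rate = scale,
                            lower.tail = FALSE)
  xs <- sort(draws)
  ks <- max(abs(cdf(xs) - seq_along(xs) / length(xs)))
  expect_lt(ks, 0.05)
})

test_that("posterior concentrates near REML on well-replicated designs", {
  d <- sim_balanced_ncii(
    s2 = c(sire = 0.3, dam = 0.3, sire_dam = 0.1, resid = 0.5),
    n_sires = 14, n_dams = 10, r = 4, seed = 33)
  fit <- ncii_lmm(ncii_formula, d)
  ch <- ncii_gibbs(ncii_formula, d, n_iter = 6000, burn_in = 1000,
                   thin = 5, seed = 3)
  reml <- c(fit$sigma2, residual = fit$sigma2_resid)
  for (pn in names(reml)) {
    h <- hpd_interval(ch$draws[, pn], 0.95)
    expect_gt(reml[[pn]], h$lower)
    expect_lt(reml[[pn]], h$upper)
  }
  # the residual variance is tightly identified: means agree closely
  expect_equal(mean(ch$draws[, "residual"]), reml[["residual"]],
               tolerance = 0.1)
})

test_that("prior and settings are validated", {
  d <- sim_balanced_ncii(n_sires = 4, n_dams = 3, r = 2, seed = 1)
  expect_error(ncii_gibbs(ncii_formula, d, prior = c(nu = -1, V = 1)),
               "nu > 0")
  expect_error(ncii_gibbs(ncii_formula, d, n_iter = 100, burn_in = 200),
               "burn_in")
  expect_error(ncii_gibbs(ncii_formula, d, n_iter = 100, burn_in = 10,
                          thin = 0), "thin")
})
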