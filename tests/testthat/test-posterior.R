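test_that("HPD intervals are the shortest windows over sorted draws", {
  h <- hpd_interval(1:100, 0.95)
  expect_equal(h$upper - h$lower, 94)      # ceiling(0.95*100) = 95 draws
  expect_equal(h$lower, 1)                 # tie broken to lowest bound

  set.seed(4)
  for (i in 1:8) {
    x <- switch(1 + i %% 4,
                rexp(80, 0.5),             # right-skewed
                rnorm(120),
                c(rnorm(50), rnorm(30, 6)),
                rlnorm(60))
    for (prob in c(0.5, 0.9, 0.95)) {
      h <- hpd_interval(x, prob)
      b <- brute_hpd(x, prob)
      expect_equal(c(h$lower, h$upper), b)
      expect_gte(mean(x >= h$lower & x <= h$upper), prob)
    }
  }
})

test_that("HPD beats equal-tail intervals on skewed samples and is affine-equivariant", {
  set.seed(9)
  x <- rexp(500, 1)
  h <- hpd_interval(x, 0.95)
  et <- unname(quantile(x, c(0.025, 0.975)))
  expect_lte(h$upper - h$lower, et[2] - et[1])

  a <- 3.2
  b <- 1.7
  h2 <- hpd_interval(a + b * x, 0.95)
  expect_equal(h2$lower, a + b * h$lower, tolerance = 1e-12)
  expect_equal(h2$upper, a + b * h$upper, tolerance = 1e-12)

  hp <- hpd_interval(rep(2.5, 40), 0.95)
  expect_equal(hp$lower, hp$upper)

  expect_error(hpd_interval(1:10), "20 draws")
  expect_error(hpd_interval(1:100, 1.2), "prob")
})

test_that("posterior modes locate the density peak", {
  set.seed(11)
  x <- rnorm(20000, 3, 1)
  expect_equal(posterior_mode(x), 3, tolerance = 0.1)
  expect_equal(posterior_mode(rep(7.1, 25)), 7.1)
  mix <- c(rnorm(7000, 0, 0.5), rnorm(3000, 5, 0.5))
  expect_equal(posterior_mode(mix), 0, tolerance = 0.3)
  expect_error(posterior_mode(1:5), "20 draws")
})

test_that("DIC identities hold and the >= 10 rule is boundary-inclusive", {
  d <- sim_balanced_ncii(n_sires = 6, n_dams = 3, r = 3, seed = 5)
  ch <- ncii_gibbs(ncii_formula, d, n_iter = 2000, burn_in = 500,
                   thin = 5, seed = 2)
  res <- dic(ch)
  expect_equal(res$pD, res$mean_deviance - res$deviance_at_mean)
  expect_equal(res$dic, res$mean_deviance + res$pD)
  expect_gt(res$pD, 0)

  expect_true(dic_compare(110, 100)$significant)     # boundary inclusive
  expect_equal(dic_compare(110, 100)$better, "b")
  expect_false(dic_compare(105, 100)$significant)
  cmp <- dic_compare(res, res)
  expect_equal(cmp$delta, 0)
  expect_equal(cmp$better, "neither")
})

test_that("stationary chains pass Heidelberger-Welch and trending chains fail", {
  pass0 <- 0L
  n_chain <- 20L
  for (s in seq_len(n_chain)) {
    set.seed(700 + s)
    hw <- heidelberger_welch(rnorm(1500, 10, 1))
    if (hw$stationarity_passed && hw$fraction_discarded == 0) {
      pass0 <- pass0 + 1L
    }
  }
  expect_gte(pass0, n_chain - 3L)  # ~5% level test

  set.seed(77)
  trend <- rnorm(1500) + seq(0, 8, length.out = 1500)
  hw_t <- heidelberger_welch(trend)
  expect_false(hw_t$stationarity_passed && hw_t$fraction_discarded == 0)

  hw_c <- heidelberger_welch(rep(3, 200))
  expect_true(hw_c$halfwidth_passed)

  # tight well-mixed chain passes the relative-halfwidth requirement
  set.seed(5)
  hw_m <- heidelberger_welch(rnorm(5000, 100, 1), eps = 0.1)
  expect_true(hw_m$halfwidth_passed)
  expect_true(hw_m$fraction_discarded %in% seq(0, 0.5, by = 0.1))

  expect_error(heidelberger_welch(rnorm(50)), "100 draws")
})
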