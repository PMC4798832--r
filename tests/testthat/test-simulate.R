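zero_var <- function() {
  z <- c(sire = 0, dam = 0, sire_dam = 0, resid = 0)
  sim_params(
    hatch_dd = trait_params(mean = 360, sigma2 = z),
    length_mm = trait_params(mean = 12, sigma2 = z, slope_hatch = 0.01),
    log_yolk_vol = trait_params(mean = 0.5, sigma2 = z,
                                slope_hatch = -0.002),
    p_mort = 0
  )
}

test_that("degenerate simulation reproduces the grand means exactly", {
  rec <- simulate_ncii(reps_min = 1, reps_max = 1, params = zero_var(),
                       seed = 5)
  expect_true(all(rec$survived))
  expect_true(all(rec$hatch_dd == 360))
  m <- !is.na(rec$length_mm)
  expect_true(any(m))
  expect_equal(rec$length_mm[m], rep(12, sum(m)))
  expect_equal(log(rec$yolk_vol_mm3[m]), rep(0.5, sum(m)),
               tolerance = 1e-10)
})

test_that("sire variance is recovered from family means", {
  # sire variance 1, everything else 0: the family mean IS the sire effect
  p <- zero_var()
  p$traits$hatch_dd$sigma2[["sire"]] <- 1
  rec <- simulate_ncii(n_dams = 1, n_sires = 500, reps_min = 1,
                       reps_max = 1, params = p, seed = 21)
  ctrl <- rec[rec$analysis_group == "control" & rec$raw_group ==
                "control_untreated", ]
  eff <- tapply(ctrl$hatch_dd, ctrl$sire_id, mean) - 360
  v <- var(eff)
  se <- sqrt(2 / (length(eff) - 1))  # SE of a normal sample variance
  expect_lt(abs(v - 1), 4 * se)
})

test_that("cross-environment correlation of sire effects follows r_g", {
  p <- zero_var()
  p$traits$hatch_dd$sigma2[["sire"]] <- 1
  # r_g = 1: identical sire effect in every analysis group
  p$traits$hatch_dd$r_g <- 1
  rec <- simulate_ncii(n_dams = 1, n_sires = 40, reps_min = 1,
                       reps_max = 1, params = p, seed = 3)
  sm <- sire_means(rec, "hatch_dd")
  # identical up to the floating-point noise of the correlation square root
  expect_true(all(abs(sm - sm[, 1]) < 1e-5))

  # r_g = 0: effects uncorrelated across groups
  p$traits$hatch_dd$r_g <- 0
  rec0 <- simulate_ncii(n_dams = 1, n_sires = 600, reps_min = 1,
                        reps_max = 1, params = p, seed = 4)
  sm0 <- sire_means(rec0, "hatch_dd")
  r12 <- cor(sm0[, 1], sm0[, 2])
  r13 <- cor(sm0[, 1], sm0[, 3])
  expect_lt(abs(r12), 4 / sqrt(nrow(sm0)))
  expect_lt(abs(r13), 4 / sqrt(nrow(sm0)))
})

test_that("mortality matches its binomial expectation", {
  p <- sim_params(p_mort = 0.005)
  rec <- simulate_ncii(reps_min = 6, reps_max = 6, params = p, seed = 9)
  n <- nrow(rec)
  expect_equal(n, 48 * 9 * 6)
  deaths <- sum(!rec$survived)
  expect_lt(abs(deaths - n * 0.005), 4 * sqrt(n * 0.005 * 0.995) + 1)
  # dead embryos carry no trait values
  expect_true(all(is.na(rec$hatch_dd[!rec$survived])))
})

test_that("group means reflect the treatment effects", {
  rec <- simulate_ncii(reps_min = 7, reps_max = 7, seed = 13)
  p <- sim_params()
  ctrl <- rec$hatch_dd[rec$analysis_group == "control"]
  hi <- rec$hatch_dd[rec$analysis_group == "AgNO3_high"]
  s2 <- p$traits$hatch_dd$sigma2
  # parental effects do not average out over only 4 dams / 12 sires:
  # var(mean) ~ sd2/4 + ss2/12 + ssd2/48 + se2/n
  se_ctrl <- 4 * sqrt(s2[["dam"]] / 4 + s2[["sire"]] / 12 +
                        s2[["sire_dam"]] / 48 + s2[["resid"]] / 1000)
  expect_lt(abs(mean(ctrl, na.rm = TRUE) - 360), se_ctrl)
  diff_hi <- mean(hi, na.rm = TRUE) - mean(ctrl, na.rm = TRUE)
  expect_lt(abs(diff_hi - (-30)), 5)
})

test_that("yolk volume follows the spheroid formula", {
  d <- 1.7
  expect_equal(yolk_volume(d, d), pi / 6 * d^3)
  expect_equal(yolk_volume(2, 1), pi / 3)
  expect_equal(yolk_volume(1, 2), 2 * pi / 3)  # width enters squared
  expect_equal(yolk_volume(2, 1, coef = 1), 2)
  expect_error(yolk_volume(0, 1), "positive")
  expect_error(yolk_volume(1, -2), "positive")
})

test_that("simulated records satisfy every structural invariant", {
  for (seed in 1:3) {
    rec <- quick_records(seed = seed)
    expect_silent(validate_records(rec))
    expect_true(all(rec$hatch_dd > 240.5, na.rm = TRUE))
    m <- !is.na(rec$yolk_vol_mm3)
    expect_equal(rec$yolk_vol_mm3[m],
                 pi / 6 * rec$yolk_len_mm[m] * rec$yolk_width_mm[m]^2,
                 tolerance = 1e-10)
  }
})

test_that("record validation catches corrupted tables", {
  rec <- quick_records(seed = 2)
  bad <- rec
  bad$hatch_dd[1] <- 100  # before treatment start
  expect_error(validate_records(bad), "240.5")
  bad2 <- rec
  i <- which(!bad2$survived)[1]
  if (is.na(i)) {
    bad2$survived[1] <- FALSE
    i <- 1
  }
  bad2$hatch_dd[i] <- 300
  expect_error(validate_records(bad2), "dead")
  bad3 <- rec
  j <- which(!is.na(bad3$yolk_vol_mm3))[1]
  bad3$yolk_vol_mm3[j] <- bad3$yolk_vol_mm3[j] * 2
  expect_error(validate_records(bad3), "inconsistent")
})

test_that("non-PSD cross-environment correlation is rejected", {
  p <- sim_params()
  R <- diag(7)
  R[1, 2] <- R[2, 1] <- 0.9
  R[1, 3] <- R[3, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- -0.9  # violates PSD
  p$traits$hatch_dd$r_g <- R
  expect_error(simulate_ncii(params = p, seed = 1), "semidefinite")
})
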