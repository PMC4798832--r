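test_that("sire means are plain cell averages with counts", {
  rec <- data.frame(
    sire_id = c("S1", "S1", "S1", "S2", "S2"),
    dam_id = "D1",
    raw_group = "control_untreated",
    analysis_group = c("control", "control", "AgNO3_low",
                       "control", "AgNO3_low"),
    replicate_index = 1,
    survived = TRUE,
    hatch_dd = c(350, 354, 360, 341, 345),
    length_mm = NA_real_, yolk_len_mm = NA_real_,
    yolk_width_mm = NA_real_, yolk_vol_mm3 = NA_real_
  )
  sm <- sire_means(rec, "hatch_dd")
  expect_equal(sm["S1", "control"], 352)
  expect_equal(sm["S1", "AgNO3_low"], 360)
  expect_equal(sm["S2", "control"], 341)
  expect_equal(attr(sm, "counts")["S1", "control"], 2L)

  # a sire absent from a group leaves a missing cell
  rec2 <- rec[-3, ]  # S1 loses its only AgNO3_low offspring
  sm2 <- sire_means(rec2, "hatch_dd")
  expect_true(is.na(sm2["S1", "AgNO3_low"]))
  expect_error(sire_means(rec, "nope"), "not found")
})

test_that("one offspring per cell returns the raw values", {
  rec <- quick_records(seed = 3, reps = 1)
  one <- rec[rec$survived & rec$raw_group == "AgNO3_low" &
               rec$dam_id == "D01", ]
  sm <- sire_means(one, "hatch_dd")
  expect_equal(unname(sm[one$sire_id, "AgNO3_low"]), one$hatch_dd)
})

test_that("correlations match hand arithmetic and Bonferroni bookkeeping", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  M <- cbind(g1 = x, g2 = y)
  rownames(M) <- sprintf("S%d", 1:5)
  attr(M, "trait") <- "hatch_dd"
  class(M) <- c("sire_means", "matrix")
  gc2 <- cross_env_correlation(M)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(gc2$corr["g1", "g2"], r_hand)
  t_hand <- r_hand * sqrt(3) / sqrt(1 - r_hand^2)
  expect_equal(gc2$p["g1", "g2"], 2 * pt(-abs(t_hand), 3))
  expect_equal(gc2$n_pairs, 1)

  # duplicated column correlates perfectly with its copy
  M3 <- cbind(M, g3 = x)
  class(M3) <- c("sire_means", "matrix")
  gc3 <- cross_env_correlation(M3)
  expect_equal(gc3$corr["g1", "g3"], 1)
  expect_equal(diag(gc3$corr), c(g1 = 1, g2 = 1, g3 = 1))
  expect_equal(gc3$corr, t(gc3$corr))
})

test_that("seven groups give 21 pairs and the 0.002 threshold", {
  rec <- quick_records(seed = 8, reps = 3)
  gc <- cross_env_correlation(sire_means(rec, "hatch_dd"))
  expect_equal(gc$n_pairs, 21)
  expect_equal(round(gc$bonferroni_alpha, 3), 0.002)
  expect_true(all(gc$corr >= -1 & gc$corr <= 1, na.rm = TRUE))
  # significance flags follow the raw p / threshold rule exactly
  expect_equal(gc$significant,
               !is.na(gc$p) & gc$p < gc$bonferroni_alpha)
})

test_that("sparse cells fall back to pairwise-complete with a warning", {
  M <- matrix(c(1, 2, NA, NA, 2, 1, NA, NA), 4, 2,
              dimnames = list(sprintf("S%d", 1:4), c("g1", "g2")))
  class(M) <- c("sire_means", "matrix")
  expect_warning(gc <- cross_env_correlation(M), "fewer than 3")
  expect_true(is.na(gc$corr["g1", "g2"]))
})

test_that("interaction suites return one LRT per interaction term", {
  rec <- quick_records(seed = 10, reps = 3)
  suite <- interaction_lrt_suite(rec, "hatch_dd", test_group = "AgNO3_high")
  expect_equal(nrow(suite), 3)
  expect_setequal(suite$term, c("sire_x_treatment", "dam_x_treatment",
                                "sire_x_dam_x_treatment"))
  expect_true(all(suite$chi2 >= 0))
  expect_true(all(suite$df >= 1))
  expect_true(all(suite$p_value >= 0 & suite$p_value <= 1))
  expect_error(
    interaction_lrt_suite(rec[rec$analysis_group == "control", ],
                          "hatch_dd", test_group = "AgNO3_high"),
    "both analysis groups")
})

test_that("sire-mean correlations attenuate with fewer offspring per cell", {
  # strong sire signal, r_g = 1: more offspring per sire per group means
  # less within-family noise, so the family-mean correlation climbs
  p <- sim_params(
    hatch_dd = trait_params(mean = 360,
                            sigma2 = c(sire = 30, dam = 5, sire_dam = 5,
                                       resid = 70), r_g = 1),
    p_mort = 0
  )
  mean_offdiag <- function(reps, seed) {
    rec <- simulate_ncii(n_sires = 12, reps_min = reps, reps_max = reps,
                         params = p, seed = seed)
    gc <- cross_env_correlation(sire_means(rec, "hatch_dd"))
    mean(gc$corr[upper.tri(gc$corr)], na.rm = TRUE)
  }
  r2 <- mean(sapply(1:3, function(s) mean_offdiag(2, 100 + s)))
  r10 <- mean(sapply(1:3, function(s) mean_offdiag(10, 200 + s)))
  expect_gt(r10, r2)
  expect_gt(r10, 0.8)   # high replication approaches the generative rho = 1
})
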