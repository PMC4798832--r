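#' Yolk-sac volume from length and width
#'
#' Prolate-spheroid volume `V = coef * L * W^2` with `coef = pi/6`, the
#' standard approximation for salmonid yolk sacs measured as one long and
#' one short axis. The coefficient is configurable to accommodate
#' alternative spheroid conventions.
#'
#' @param yolk_len_mm Long axis (mm), positive.
#' @param yolk_width_mm Short axis (mm), positive.
#' @param coef Volume coefficient; default `pi/6`.
#' @return Volume in mm^3. Vectorized; the argument order matters (the
#'   width enters squared).
#' @examples
#' yolk_volume(2, 1)  # pi/3
#' @export
yolk_volume <- function(yolk_len_mm, yolk_width_mm, coef = pi / 6) {
  if (any(!is.finite(yolk_len_mm)) || any(!is.finite(yolk_width_mm)) ||
      any(yolk_len_mm <= 0) || any(yolk_width_mm <= 0)) {
    stop("yolk dimensions must be positive and finite", call. = FALSE)
  }
  coef * yolk_len_mm * yolk_width_mm^2
}

# Draw one matrix of sire effects (n_sires x n_groups) with variance s2
# and cross-group correlation R (rows are independent sires).
draw_sire_effects <- function(n_sires, groups, s2, r_g) {
  g <- length(groups)
  R <- if (is.matrix(r_g)) r_g else exch_corr(g, r_g)
  A <- psd_sqrt(R, "r_g")
  M <- matrix(stats::rnorm(n_sires * g), n_sires, g) %*% A * sqrt(s2)
  colnames(M) <- groups
  M
}

#' Simulate phenotypes on an embryo allocation
#'
#' Generates survival and trait values for every allocated embryo under the
#' crossed-random-effects model the downstream analysis assumes: for each
#' Gaussian trait, `y = mu + tau[group] + s + d + sd + e` with independent
#' zero-mean Gaussian sire, dam, sire-by-dam and residual effects; sire
#' effects are drawn jointly across analysis groups with correlation `r_g`
#' (so genotype-by-environment strength is controlled by `r_g`); larval
#' length and log yolk volume additionally regress on centered hatching
#' time. Survival is Bernoulli with logit mean `qlogis(1 - p_mort)` plus
#' optional logit-scale family random effects. Dead embryos carry no trait
#' values; size traits are observed only on a random measurement subset
#' per analysis group. Hatching is expressed in degree days (6.5 degC x
#' days); treatment started at 240.5 degree days, so observed hatch times
#' exceed that.
#'
#' @param allocation Embryo allocation table from [allocate_embryos()].
#' @param params A [sim_params()] object.
#' @param seed Integer seed; one seeded stream drives all randomness.
#' @return A data frame of embryo records with columns `sire_id`,
#'   `dam_id`, `raw_group`, `analysis_group`, `replicate_index`,
#'   `survived`, `hatch_dd`, `length_mm`, `yolk_len_mm`, `yolk_width_mm`,
#'   `yolk_vol_mm3`. The seed is recorded in `attr(, "seed")`.
#' @export
simulate_phenotypes <- function(allocation, params = sim_params(), seed = 1L) {
  groups <- unique(allocation$analysis_group)
  ord <- silver_treatments()$analysis_groups
  groups <- c(intersect(ord, groups), setdiff(groups, ord))
  validate_sim_params(params, n_groups = length(groups))
  sires <- sort(unique(allocation$sire_id))
  dams <- sort(unique(allocation$dam_id))
  fam <- paste(allocation$sire_id, allocation$dam_id, sep = ":")
  fams <- sort(unique(fam))
  n <- nrow(allocation)
  i_s <- match(allocation$sire_id, sires)
  i_d <- match(allocation$dam_id, dams)
  i_f <- match(fam, fams)
  i_g <- match(allocation$analysis_group, groups)

  with_seed(seed, {
    # survival first: logit(P(survive)) = qlogis(1 - p_mort) + effects
    ms <- params$mort_sigma2
    eta <- stats::qlogis(1 - params$p_mort) +
      stats::rnorm(length(sires), 0, sqrt(ms[["sire"]]))[i_s] +
      stats::rnorm(length(dams), 0, sqrt(ms[["dam"]]))[i_d] +
      stats::rnorm(length(fams), 0, sqrt(ms[["sire_dam"]]))[i_f]
    survived <- stats::runif(n) < stats::plogis(eta)

    gauss_trait <- function(tp) {
      s_mat <- draw_sire_effects(length(sires), groups, tp$sigma2[["sire"]],
                                 tp$r_g)
      d_eff <- stats::rnorm(length(dams), 0, sqrt(tp$sigma2[["dam"]]))
      f_eff <- stats::rnorm(length(fams), 0, sqrt(tp$sigma2[["sire_dam"]]))
      tau <- rep(0, length(groups))
      names(tau) <- groups
      if (length(tp$effects)) {
        bad <- setdiff(names(tp$effects), groups)
        if (length(bad)) {
          stop("treatment effects name unknown groups: ",
               paste(bad, collapse = ", "), call. = FALSE)
        }
        tau[names(tp$effects)] <- tp$effects
      }
      tp$mean + tau[i_g] + s_mat[cbind(i_s, i_g)] + d_eff[i_d] +
        f_eff[i_f] + stats::rnorm(n, 0, sqrt(tp$sigma2[["resid"]]))
    }

    hatch <- gauss_trait(params$traits$hatch_dd)
    hatch <- pmax(hatch, 240.6)  # treatment started at 240.5 DD
    hatch[!survived] <- NA_real_

    h_centered <- hatch - mean(hatch, na.rm = TRUE)
    len <- gauss_trait(params$traits$length_mm) +
      params$traits$length_mm$slope_hatch * h_centered
    lyv <- gauss_trait(params$traits$log_yolk_vol) +
      params$traits$log_yolk_vol$slope_hatch * h_centered

    # per-analysis-group measurement subset among survivors
    measured <- rep(FALSE, n)
    for (g in groups) {
      cand <- which(survived & allocation$analysis_group == g)
      k <- round(params$measurement_fraction * length(cand))
      if (k > 0) measured[sample(cand, k)] <- TRUE
    }
    len[!measured] <- NA_real_
    lyv[!measured] <- NA_real_

    aspect <- pmax(stats::rnorm(n, params$yolk_aspect[["mean"]],
                                params$yolk_aspect[["sd"]]), 1.05)
    vol <- ylen <- width <- rep(NA_real_, n)
    if (any(measured)) {
      v_m <- exp(lyv[measured])
      w_m <- (v_m / (params$yolk_coef * aspect[measured]))^(1 / 3)
      l_m <- aspect[measured] * w_m
      width[measured] <- w_m
      ylen[measured] <- l_m
      vol[measured] <- yolk_volume(l_m, w_m, coef = params$yolk_coef)
    }

    out <- data.frame(
      sire_id = allocation$sire_id,
      dam_id = allocation$dam_id,
      raw_group = allocation$raw_group,
      analysis_group = allocation$analysis_group,
      replicate_index = allocation$replicate_index,
      survived = survived,
      hatch_dd = hatch,
      length_mm = len,
      yolk_len_mm = ylen,
      yolk_width_mm = width,
      yolk_vol_mm3 = vol,
      stringsAsFactors = FALSE
    )
    attr(out, "seed") <- seed
    out
  })
}

#' Simulate a complete NC II silver-exposure data set
#'
#' Convenience wrapper chaining [ncii_design()], [allocate_embryos()] and
#' [simulate_phenotypes()] at the scale of the motivating experiment
#' (4 dams x 12 sires, 9 raw treatment groups pooled to 7 analysis groups,
#' 5-7 replicates per family per treatment).
#'
#' @param n_dams,n_sires Parent counts.
#' @param reps_min,reps_max Replicates per family per raw treatment group.
#' @param params Generative parameters, see [sim_params()].
#' @param scheme Treatment scheme, see [silver_treatments()].
#' @param seed Integer seed for allocation and phenotypes.
#' @return A validated embryo-record data frame (see
#'   [simulate_phenotypes()]).
#' @export
simulate_ncii <- function(n_dams = 4, n_sires = 12, reps_min = 5,
                          reps_max = 7, params = sim_params(),
                          scheme = silver_treatments(), seed = 1L) {
  design <- ncii_design(n_dams, n_sires)
  alloc <- allocate_embryos(design, scheme, reps_min, reps_max, seed = seed)
  rec <- simulate_phenotypes(alloc, params, seed = seed + 1L)
  validate_records(rec)
  rec
}
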