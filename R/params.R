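#' Per-trait generative parameters
#'
#' Bundles the generative model for one Gaussian trait in the NC II
#' simulator: grand mean, fixed treatment effects on the analysis groups
#' (control fixed at 0), the four variance components, the
#' cross-environment correlation of sire effects, and (for size traits) a
#' linear dependence on centered hatching time.
#'
#' @param mean Grand mean on the trait scale (degree days, mm, or log mm^3).
#' @param effects Named numeric vector of treatment effects per analysis
#'   group; groups not named default to 0 and the control must be 0.
#' @param sigma2 Named numeric vector with components `sire`, `dam`,
#'   `sire_dam`, `resid` (trait units squared), all non-negative.
#' @param r_g Cross-environment correlation of sire effects: either a
#'   single correlation applied exchangeably to all pairs of analysis
#'   groups, or a full symmetric positive-semidefinite matrix with unit
#'   diagonal (one row/column per analysis group).
#' @param slope_hatch Regression slope of the trait on centered hatching
#'   time (trait units per degree day); 0 disables the covariate.
#' @return A list of class `"ncii_trait_params"`.
#' @export
trait_params <- function(mean, effects = numeric(0),
                         sigma2 = c(sire = 0.25, dam = 0.25,
                                    sire_dam = 0.1, resid = 0.4),
                         r_g = 1, slope_hatch = 0) {
  need <- c("sire", "dam", "sire_dam", "resid")
  if (!all(need %in% names(sigma2))) {
    stop("sigma2 must name components: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sigma2 <- sigma2[need]
  if (any(sigma2 < 0)) stop("variance components must be >= 0", call. = FALSE)
  structure(
    list(mean = mean, effects = effects, sigma2 = sigma2,
         r_g = r_g, slope_hatch = slope_hatch),
    class = "ncii_trait_params"
  )
}

#' Simulation parameters for the NC II silver-exposure experiment
#'
#' Default generative settings for the three Gaussian traits (hatching
#' time in degree days, larval length in mm, log yolk-sac volume in log
#' mm^3) plus rare binary mortality and the measurement-subset scheme for
#' size traits. The defaults are synthetic: no variance-component table is
#' available for the original data, so they are chosen to reproduce the
#' qualitative pattern of the motivating study — heritability near 0.8 for
#' hatching time, dam-dominated variance for size traits, earlier hatching
#' under high-dose silver (strongest for ionic silver), larger yolk sacs at
#' high-dose AgNO3, smaller larvae among early hatchers, near-unity
#' cross-environment sire correlation for hatching time, and ~0.5%
#' treatment-independent mortality.
#'
#' @param hatch_dd,length_mm,log_yolk_vol Per-trait settings, see
#'   [trait_params()].
#' @param p_mort Baseline mortality probability.
#' @param mort_sigma2 Logit-scale random-effect variances for mortality
#'   (named `sire`, `dam`, `sire_dam`); default all 0, matching the
#'   essentially family-independent 0.5% mortality observed.
#' @param measurement_fraction Fraction of surviving embryos per analysis
#'   group whose length and yolk dimensions are measured.
#' @param yolk_coef Coefficient of the yolk volume formula
#'   `V = yolk_coef * L * W^2`; default `pi/6` (prolate spheroid).
#' @param yolk_aspect Mean and SD of the yolk length/width aspect ratio
#'   used to split a simulated volume into the two measured dimensions.
#' @return A list of class `"ncii_sim_params"`.
#' @export
sim_params <- function(
    hatch_dd = trait_params(
      mean = 360,
      effects = c(AgNO3_low = -0.5, AgNO3_high = -30,
                  AgNP20_low = -4, AgNP20_high = -12,
                  AgNP100_low = -4, AgNP100_high = -10),
      sigma2 = c(sire = 30, dam = 40, sire_dam = 10, resid = 70),
      r_g = 0.95),
    length_mm = trait_params(
      mean = 12,
      effects = numeric(0),
      sigma2 = c(sire = 0.005, dam = 0.15, sire_dam = 0.005, resid = 0.08),
      r_g = 0.5, slope_hatch = 0.01),
    log_yolk_vol = trait_params(
      mean = 0.5,
      effects = c(AgNO3_high = 0.15),
      sigma2 = c(sire = 0.002, dam = 0.04, sire_dam = 0.002, resid = 0.03),
      r_g = 0.5, slope_hatch = -0.002),
    p_mort = 0.005,
    mort_sigma2 = c(sire = 0, dam = 0, sire_dam = 0),
    measurement_fraction = 0.17,
    yolk_coef = pi / 6,
    yolk_aspect = c(mean = 1.5, sd = 0.15)) {
  out <- structure(
    list(traits = list(hatch_dd = hatch_dd, length_mm = length_mm,
                       log_yolk_vol = log_yolk_vol),
         p_mort = p_mort, mort_sigma2 = mort_sigma2,
         measurement_fraction = measurement_fraction,
         yolk_coef = yolk_coef, yolk_aspect = yolk_aspect),
    class = "ncii_sim_params"
  )
  validate_sim_params(out)
  out
}

#' Validate simulation parameters
#'
#' Checks non-negative variances, a mortality probability in `[0, 1]`, a
#' measurement fraction in `(0, 1]`, and per trait a symmetric positive
#' semidefinite cross-environment correlation with unit diagonal.
#'
#' @param params A [sim_params()] object.
#' @param n_groups Number of analysis groups a matrix `r_g` must span.
#' @return `params`, invisibly; errors describe the offending field.
#' @export
validate_sim_params <- function(params, n_groups = 7L) {
  stopifnot(inherits(params, "ncii_sim_params"))
  if (params$p_mort < 0 || params$p_mort > 1) {
    stop("p_mort must lie in [0, 1]", call. = FALSE)
  }
  if (any(params$mort_sigma2 < 0)) {
    stop("mortality random-effect variances must be >= 0", call. = FALSE)
  }
  if (params$measurement_fraction <= 0 || params$measurement_fraction > 1) {
    stop("measurement_fraction must lie in (0, 1]", call. = FALSE)
  }
  for (tn in names(params$traits)) {
    tp <- params$traits[[tn]]
    if (any(tp$sigma2 < 0)) {
      stop("negative variance component for trait ", tn, call. = FALSE)
    }
    rg <- tp$r_g
    if (is.matrix(rg)) {
      if (nrow(rg) != n_groups || ncol(rg) != n_groups) {
        stop("r_g matrix for ", tn, " must be ", n_groups, "x", n_groups,
             call. = FALSE)
      }
      if (max(abs(rg - t(rg))) > 1e-10 || max(abs(diag(rg) - 1)) > 1e-10) {
        stop("r_g for ", tn, " must be symmetric with unit diagonal",
             call. = FALSE)
      }
      ev <- eigen(rg, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8) {
        stop("r_g for ", tn, " is not positive semidefinite", call. = FALSE)
      }
    } else if (length(rg) != 1L || rg < -1 / (n_groups - 1) - 1e-12 || rg > 1) {
      stop("scalar r_g for ", tn, " must give a valid exchangeable ",
           "correlation", call. = FALSE)
    }
  }
  invisible(params)
}
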