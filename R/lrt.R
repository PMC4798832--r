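#' Likelihood-ratio test between nested mixed models
#'
#' Compares a full and a reduced fit on the same data:
#' `chi2 = max(0, 2 * (logLik_full - logLik_reduced))`, degrees of freedom
#' equal to the number of dropped parameters, and a p-value from the
#' chi-squared reference distribution (the convention of the motivating
#' analysis). For variance components tested on their boundary, the
#' conservative naive chi-squared p-value is reported alongside a 50:50
#' chi-bar-squared mixture p-value (`p_boundary`).
#'
#' Both fits must share the estimation flavor; REML comparisons
#' additionally require identical fixed-effects structure (REML
#' likelihoods are not comparable otherwise) — test fixed effects with
#' ML fits.
#'
#' @param full,reduced Fitted models of class `ncii_lmm` (or both
#'   `ncii_glmm`), the reduced one nested in the full one.
#' @return An object of class `"ncii_lrt"`: `chi2`, `df`, `p_value`,
#'   `p_boundary`, `full_loglik`, `reduced_loglik`, `flavor`.
#' @export
lrt <- function(full, reduced) {
  same_class <- (inherits(full, "ncii_lmm") && inherits(reduced, "ncii_lmm")) ||
    (inherits(full, "ncii_glmm") && inherits(reduced, "ncii_glmm"))
  if (!same_class) {
    stop("full and reduced must both be ncii_lmm (or both ncii_glmm) fits",
         call. = FALSE)
  }
  if (full$n_obs != reduced$n_obs) {
    stop("fits use different numbers of rows; refit on common data",
         call. = FALSE)
  }
  is_lmm <- inherits(full, "ncii_lmm")
  flavor <- if (!is_lmm) "ML" else if (full$REML) "REML" else "ML"
  if (is_lmm && full$REML != reduced$REML) {
    stop("fits mix REML and ML likelihoods", call. = FALSE)
  }
  fixed_equal <- identical(colnames(full$X), colnames(reduced$X))
  if (is_lmm && full$REML && !fixed_equal) {
    stop("REML likelihoods are not comparable across different fixed ",
         "effects; refit with REML = FALSE", call. = FALSE)
  }
  if (!all(reduced$random_labels %in% full$random_labels) ||
      !all(colnames(reduced$X) %in% colnames(full$X))) {
    stop("reduced model is not nested in the full model", call. = FALSE)
  }
  df <- (length(full$beta) + length(full$sigma2)) -
    (length(reduced$beta) + length(reduced$sigma2))
  if (df < 0) stop("reduced model has more parameters than full",
                   call. = FALSE)
  chi2 <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) as.numeric(chi2 <= 1e-8) else
    stats::pchisq(chi2, df, lower.tail = FALSE)
  if (df == 0 && chi2 <= 1e-8) p <- 1
  # 50:50 mixture of chi2_df and chi2_{df-1} (df-1 = 0 -> point mass at 0)
  p_b <- if (df >= 1) {
    p_hi <- stats::pchisq(chi2, df, lower.tail = FALSE)
    p_lo <- if (df > 1) stats::pchisq(chi2, df - 1, lower.tail = FALSE)
            else as.numeric(chi2 <= 1e-8)
    0.5 * p_hi + 0.5 * p_lo
  } else p
  structure(list(chi2 = chi2, df = df, p_value = p, p_boundary = p_b,
                 full_loglik = full$loglik, reduced_loglik = reduced$loglik,
                 flavor = flavor),
            class = "ncii_lrt")
}

#' @export
print.ncii_lrt <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test (%s): chi2 = %.4g, df = %d, p = %.4g\n",
              x$flavor, x$chi2, x$df, x$p_value))
  cat(sprintf("  boundary-corrected (50:50 mixture) p = %.4g\n", x$p_boundary))
  invisible(x)
}

#' @export
anova.ncii_lmm <- function(object, ...) {
  others <- list(...)
  others <- others[vapply(others, inherits, logical(1), "ncii_lmm")]
  if (length(others) != 1L) {
    stop("supply exactly two fitted models: anova(full, reduced)",
         call. = FALSE)
  }
  a <- object
  b <- others[[1L]]
  np <- function(f) length(f$beta) + length(f$sigma2)
  if (np(a) >= np(b)) lrt(a, b) else lrt(b, a)
}
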