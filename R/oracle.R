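#' Expected-mean-squares variance components for a balanced NC II table
#'
#' Method-of-moments estimator for the balanced full-factorial design:
#' the sire, dam, sire-by-dam and residual mean squares are equated to
#' their expectations, giving closed-form component estimates
#' `sigma2_e = MS_E`, `sigma2_sd = (MS_SD - MS_E)/r`,
#' `sigma2_s = (MS_S - MS_SD)/(r * n_dams)` and
#' `sigma2_d = (MS_D - MS_SD)/(r * n_sires)`. Negative solutions are
#' reported as-is (no truncation): this estimator serves as an
#' independent closed-form check on the likelihood-based fits.
#'
#' @param data Data frame with one row per observation.
#' @param response Name of the numeric response column.
#' @param sire,dam Names of the sire and dam identifier columns.
#' @return A list of class `"ncii_anova"`: `sigma2` (named vector,
#'   untruncated), `mean_squares`, `df`, `r` (replicates per cell),
#'   `n_sires`, `n_dams`.
#' @export
anova_ncii <- function(data, response, sire = "sire_id", dam = "dam_id") {
  y <- data[[response]]
  if (is.null(y)) stop("response column not found: ", response, call. = FALSE)
  if (any(is.na(y))) {
    stop("balanced oracle requires no missing responses", call. = FALSE)
  }
  fs <- factor(data[[sire]])
  fd <- factor(data[[dam]])
  counts <- table(fs, fd)
  r <- counts[1L]
  if (any(counts != r) || r < 2) {
    stop("oracle requires equal replicates (>= 2) in every sire x dam cell",
         call. = FALSE)
  }
  s <- nlevels(fs)
  d <- nlevels(fd)
  gm <- mean(y)
  cell <- tapply(y, list(fs, fd), mean)
  ms <- rowMeans(cell)   # sire means
  md <- colMeans(cell)   # dam means
  ss_s <- d * r * sum((ms - gm)^2)
  ss_d <- s * r * sum((md - gm)^2)
  ss_sd <- r * sum((sweep(sweep(cell, 1, ms), 2, md) + gm)^2)
  ss_e <- sum((y - cell[cbind(fs, fd)])^2)
  df <- c(sire = s - 1, dam = d - 1, sire_dam = (s - 1) * (d - 1),
          resid = s * d * (r - 1))
  msq <- c(sire = ss_s, dam = ss_d, sire_dam = ss_sd, resid = ss_e) / df
  sigma2 <- c(
    sire = (msq[["sire"]] - msq[["sire_dam"]]) / (r * d),
    dam = (msq[["dam"]] - msq[["sire_dam"]]) / (r * s),
    sire_dam = (msq[["sire_dam"]] - msq[["resid"]]) / r,
    resid = msq[["resid"]]
  )
  structure(list(sigma2 = sigma2, mean_squares = msq, df = df,
                 r = as.integer(r), n_sires = s, n_dams = d),
            class = "ncii_anova")
}

#' @export
print.ncii_anova <- function(x, digits = 4, ...) {
  cat(sprintf("Balanced NC II expected-mean-squares estimates (%d sires x %d dams, r = %d)\n",
              x$n_sires, x$n_dams, x$r))
  print(round(x$sigma2, digits))
  invisible(x)
}
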