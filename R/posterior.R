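#' Highest posterior density interval
#'
#' Shortest contiguous interval over the sorted draws containing
#' `ceiling(prob * n)` draws. Ties in width are broken toward the lowest
#' lower bound, making the result deterministic.
#'
#' @param draws Numeric vector of at least 20 posterior draws.
#' @param prob Target probability mass, in (0, 1); default 0.95.
#' @return A list of class `"ncii_hpd"` with `lower`, `upper`, `prob`.
#' @examples
#' hpd_interval(1:100, 0.95)
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 20L) stop("need at least 20 draws", call. = FALSE)
  if (prob <= 0 || prob >= 1) stop("prob must be in (0, 1)", call. = FALSE)
  x <- sort(draws)
  k <- ceiling(prob * n)
  if (k >= n) {
    out <- list(lower = x[1L], upper = x[n], prob = prob)
  } else {
    widths <- x[k:n] - x[1:(n - k + 1L)]
    i <- which.min(widths)  # first minimal window -> lowest lower bound
    out <- list(lower = x[i], upper = x[i + k - 1L], prob = prob)
  }
  structure(out, class = "ncii_hpd")
}

#' @export
print.ncii_hpd <- function(x, digits = 4, ...) {
  cat(sprintf("%g%% HPD interval: [%.*g, %.*g]\n", 100 * x$prob,
              digits, x$lower, digits, x$upper))
  invisible(x)
}

#' Posterior mode of a sample
#'
#' Argmax of a Gaussian kernel density estimate with Silverman's
#' rule-of-thumb bandwidth over a 512-point grid spanning the draws.
#' Constant samples return the constant.
#'
#' @param draws Numeric vector of at least 20 draws.
#' @return The estimated mode (scalar).
#' @export
posterior_mode <- function(draws) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 20L) stop("need at least 20 draws", call. = FALSE)
  if (max(draws) - min(draws) < .Machine$double.eps * max(abs(draws), 1)) {
    return(draws[1L])
  }
  d <- stats::density(draws, bw = "nrd0", n = 512L)
  d$x[which.max(d$y)]
}

#' Deviance information criterion of a Gibbs chain
#'
#' Conditional-deviance DIC: the deviance is minus twice the Gaussian
#' log-likelihood conditional on the location effects (fixed plus random)
#' and the residual variance. The effective parameter count is
#' `pD = mean(D) - D(posterior means)` and `DIC = mean(D) + pD`.
#'
#' @param chain A [ncii_gibbs()] chain.
#' @return An object of class `"ncii_dic"`: `dic`, `mean_deviance`,
#'   `pD`, `deviance_at_mean`.
#' @export
dic <- function(chain) {
  if (!inherits(chain, "ncii_gibbs")) {
    stop("dic() expects an ncii_gibbs chain", call. = FALSE)
  }
  mean_dev <- mean(chain$deviance)
  pD <- mean_dev - chain$dev_at_mean
  structure(list(dic = mean_dev + pD, mean_deviance = mean_dev, pD = pD,
                 deviance_at_mean = chain$dev_at_mean),
            class = "ncii_dic")
}

#' @export
print.ncii_dic <- function(x, digits = 4, ...) {
  cat(sprintf("DIC = %.*f (mean deviance %.*f, pD %.*f)\n",
              digits, x$dic, digits, x$mean_deviance, digits, x$pD))
  invisible(x)
}

#' Compare two models by DIC
#'
#' Applies the working rule that a DIC difference of at least 10 marks a
#' significant difference in model fit (boundary inclusive).
#'
#' @param dic_a,dic_b [dic()] results (or plain numbers).
#' @param threshold Difference declared significant; default 10.
#' @return List with `delta` (`dic_a - dic_b`), `significant`, `better`
#'   (`"a"`, `"b"` or `"neither"`).
#' @export
dic_compare <- function(dic_a, dic_b, threshold = 10) {
  a <- if (inherits(dic_a, "ncii_dic")) dic_a$dic else as.numeric(dic_a)
  b <- if (inherits(dic_b, "ncii_dic")) dic_b$dic else as.numeric(dic_b)
  delta <- a - b
  sig <- abs(delta) >= threshold
  list(delta = delta, significant = sig,
       better = if (!sig) "neither" else if (delta < 0) "a" else "b")
}

# Spectral density of a chain at frequency zero, via an AR fit (the
# variance of the sample mean of a correlated chain is spec0 / n).
spectrum0_ar <- function(x) {
  x <- as.numeric(x)
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(0)
  fit <- tryCatch(
    stats::ar(x, aic = TRUE, order.max = min(30L, length(x) - 2L)),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$order == 0L) {
    if (is.null(fit)) v else fit$var.pred
  } else {
    fit$var.pred / (1 - sum(fit$ar))^2
  }
}

# Asymptotic CDF of the Cramer-von Mises statistic (series expansion with
# Bessel-K terms; standard numerical evaluation).
pcramer <- function(q, eps = 1e-5) {
  q <- pmax(q, 1e-10)
  log_eps <- log(eps)
  y <- rep(0, length(q))
  for (k in 0:3) {
    z <- gamma(k + 0.5) * sqrt(4 * k + 1) /
      (gamma(k + 1) * pi^1.5 * sqrt(q))
    u <- (4 * k + 1)^2 / (16 * q)
    term <- ifelse(u > -log_eps, 0,
                   z * exp(-u) * besselK(x = u, nu = 0.25))
    y <- y + term
  }
  pmin(pmax(y, 0), 1)
}

#' Heidelberger-Welch convergence diagnostic
#'
#' Stationarity half of the test: a Cramer-von Mises statistic on the
#' standardized cumulative-sum (Brownian bridge) process of the chain,
#' with the long-run variance estimated by the spectral density at zero
#' frequency from an AR fit to the second half of the chain. If the test
#' rejects at level `alpha`, the initial 10% of the chain is discarded
#' and the test repeated, up to half the chain. Halfwidth half: on the
#' portion passing stationarity, the mean passes if half the 95%
#' confidence interval of the mean is at most `eps` times its absolute
#' value.
#'
#' @param draws Numeric chain of at least 100 draws.
#' @param alpha Stationarity test level; default 0.05.
#' @param eps Relative halfwidth tolerance; default 0.1.
#' @return An object of class `"ncii_hw"`: `stationarity_passed`,
#'   `fraction_discarded` (0, 0.1, ..., 0.5), `cvm_statistic`,
#'   `cvm_p`, `halfwidth_passed`, `mean`, `halfwidth`.
#' @export
heidelberger_welch <- function(draws, alpha = 0.05, eps = 0.1) {
  x <- as.numeric(draws)
  n <- length(x)
  if (n < 100L) stop("need at least 100 draws", call. = FALSE)
  s0 <- spectrum0_ar(x[(n %/% 2 + 1L):n])
  passed <- FALSE
  frac <- 0
  cvm <- NA_real_
  cvm_p <- NA_real_
  start <- 1L
  for (drop10 in 0:5) {
    start <- 1L + floor(n * drop10 / 10)
    xs <- x[start:n]
    nw <- length(xs)
    if (s0 <= 0) {  # constant chain: trivially stationary
      passed <- TRUE
      frac <- drop10 / 10
      cvm <- 0
      cvm_p <- 0
      break
    }
    S <- cumsum(xs)
    t_idx <- seq_len(nw)
    B <- (S - t_idx * mean(xs)) / sqrt(nw * s0)
    cvm <- sum(B^2) / nw
    cvm_p <- pcramer(cvm)
    if (cvm_p < 1 - alpha) {
      passed <- TRUE
      frac <- drop10 / 10
      break
    }
  }
  if (!passed) {
    frac <- 0.5
    start <- 1L + floor(n * 0.5)
  }
  kept <- x[start:n]
  m <- mean(kept)
  hw <- 1.96 * sqrt(spectrum0_ar(kept) / length(kept))
  structure(list(
    stationarity_passed = passed,
    fraction_discarded = frac,
    cvm_statistic = cvm,
    cvm_p = cvm_p,
    halfwidth_passed = is.finite(hw) && hw <= eps * abs(m),
    mean = m,
    halfwidth = hw
  ), class = "ncii_hw")
}

#' @export
print.ncii_hw <- function(x, ...) {
  cat(sprintf(
    "Heidelberger-Welch: stationarity %s (CvM = %.4g, discarded %.0f%%); halfwidth %s (mean %.4g, halfwidth %.4g)\n",
    if (x$stationarity_passed) "PASSED" else "FAILED",
    x$cvm_statistic, 100 * x$fraction_discarded,
    if (x$halfwidth_passed) "PASSED" else "FAILED", x$mean, x$halfwidth))
  invisible(x)
}
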