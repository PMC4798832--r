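#' Blocked Gibbs sampler for Gaussian mixed models
#'
#' Bayesian counterpart of [ncii_lmm()]: the fixed and random effects are
#' sampled jointly from their multivariate-normal full conditional (flat
#' prior on the fixed effects), and each variance component — including
#' the residual — from its scaled-inverse-gamma full conditional under an
#' inverse-gamma prior. The prior "(nu, V)" follows the convention of the
#' animal-model MCMC literature: inverse-gamma with shape `nu/2` and scale
#' `nu * V / 2`, so the full conditional of a component with `m_k` levels
#' and effect vector `u_k` has shape `(nu + m_k)/2` and scale
#' `(nu * V + sum(u_k^2))/2`. The default `nu = 0.002, V = 1` is a
#' conventional weak prior.
#'
#' Defaults are desk-scale (50,000 iterations, 5,000 burn-in, thinning
#' 10); production-scale settings in the millions are supported through
#' the same arguments and change Monte Carlo error only.
#'
#' @param formula Mixed formula as in [ncii_lmm()] (Gaussian response).
#' @param data Data frame.
#' @param prior Named vector `c(nu = ..., V = ...)`, both positive,
#'   applied to every variance component.
#' @param n_iter,burn_in,thin Chain settings; `burn_in < n_iter`,
#'   `thin >= 1`. The retained draw count is
#'   `floor((n_iter - burn_in)/thin)`.
#' @param seed Integer seed; chains are exactly reproducible given the
#'   seed.
#' @return An object of class `"ncii_gibbs"`: `draws` (matrix of retained
#'   draws: one column per variance component, `residual`, and each fixed
#'   effect), `deviance` (conditional deviance per retained draw),
#'   `theta_mean` / `sigma2e_mean` (posterior means of location effects
#'   and residual variance, for DIC), `dev_at_mean`, `settings`, `prior`.
#' @seealso [hpd_interval()], [posterior_mode()], [dic()],
#'   [heidelberger_welch()], [decompose_posterior()].
#' @export
ncii_gibbs <- function(formula, data, prior = c(nu = 0.002, V = 1),
                       n_iter = 50000L, burn_in = 5000L, thin = 10L,
                       seed = 1L) {
  nu <- prior[["nu"]]
  Vp <- prior[["V"]]
  if (!is.finite(nu) || !is.finite(Vp) || nu <= 0 || Vp <= 0) {
    stop("prior requires nu > 0 and V > 0", call. = FALSE)
  }
  if (burn_in >= n_iter || thin < 1) {
    stop("need burn_in < n_iter and thin >= 1", call. = FALSE)
  }
  mats <- build_mixed_matrices(formula, data)
  y <- mats$y
  X <- mats$X
  Zs <- mats$Zs
  q <- length(Zs)
  # q = 0 (no random terms) is allowed: the sampler then alternates the
  # fixed effects and the residual variance, whose marginal posterior is
  # available in closed form — a conjugacy check point.
  W <- if (q > 0L) cbind(X, do.call(cbind, Zs)) else X
  n <- length(y)
  p <- ncol(X)
  m <- ncol(W) - ncol(X)
  m_k <- vapply(Zs, ncol, integer(1))
  term_of_col <- rep(seq_len(q), m_k)
  WtW <- crossprod(W)
  Wty <- crossprod(W, y)

  n_keep <- floor((n_iter - burn_in) / thin)
  par_names <- c(mats$labels, "residual", colnames(X))
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  dev_keep <- numeric(n_keep)
  theta_sum <- numeric(p + m)
  s2e_sum <- 0

  with_seed(seed, {
    vy <- stats::var(y)
    s2 <- rep(vy / (q + 1), q)
    s2e <- vy / (q + 1)
    kept <- 0L
    for (it in seq_len(n_iter)) {
      # joint draw of (beta, u) | variances
      dinv <- c(rep(0, p), if (q > 0L) 1 / s2[term_of_col])
      M <- WtW / s2e
      diag(M) <- diag(M) + dinv + 1e-12
      R <- chol(M)
      mu <- backsolve(R, backsolve(R, Wty / s2e, transpose = TRUE))
      theta <- mu + backsolve(R, stats::rnorm(p + m))
      u <- if (m > 0L) theta[(p + 1):(p + m)] else numeric(0)
      e <- y - as.numeric(W %*% theta)
      # residual variance | effects
      s2e <- (nu * Vp + sum(e * e)) /
        (2 * stats::rgamma(1, shape = (nu + n) / 2, rate = 1))
      # each component variance | its effects
      for (k in seq_len(q)) {
        uk <- u[term_of_col == k]
        s2[k] <- (nu * Vp + sum(uk * uk)) /
          (2 * stats::rgamma(1, shape = (nu + m_k[k]) / 2, rate = 1))
      }
      if (it > burn_in && (it - burn_in) %% thin == 0L) {
        kept <- kept + 1L
        if (kept <= n_keep) {
          draws[kept, ] <- c(s2, s2e, theta[seq_len(p)])
          dev_keep[kept] <- n * log(2 * pi * s2e) + sum(e * e) / s2e
          theta_sum <- theta_sum + theta
          s2e_sum <- s2e_sum + s2e
        }
      }
    }
  })
  theta_mean <- theta_sum / n_keep
  s2e_mean <- s2e_sum / n_keep
  e_mean <- y - as.numeric(W %*% theta_mean)
  dev_at_mean <- n * log(2 * pi * s2e_mean) + sum(e_mean^2) / s2e_mean
  structure(list(
    draws = draws,
    deviance = dev_keep,
    theta_mean = theta_mean,
    sigma2e_mean = s2e_mean,
    dev_at_mean = dev_at_mean,
    settings = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                    seed = seed),
    prior = c(nu = nu, V = Vp),
    formula = formula,
    random_labels = mats$labels,
    n_obs = n
  ), class = "ncii_gibbs")
}

#' @export
print.ncii_gibbs <- function(x, ...) {
  cat(sprintf(
    "Gibbs chain: %d retained draws (%d iterations, burn-in %d, thin %d, seed %d)\n",
    nrow(x$draws), x$settings$n_iter, x$settings$burn_in, x$settings$thin,
    x$settings$seed))
  cat("  parameters:", paste(colnames(x$draws), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ncii_gibbs <- function(object, prob = 0.95, ...) {
  draws <- object$draws
  tab <- t(apply(draws, 2L, function(v) {
    h <- hpd_interval(v, prob = prob)
    c(mean = mean(v), mode = posterior_mode(v),
      lower = h$lower, upper = h$upper)
  }))
  colnames(tab) <- c("mean", "mode",
                     sprintf("lower%g", 100 * prob),
                     sprintf("upper%g", 100 * prob))
  structure(list(table = tab, settings = object$settings,
                 prior = object$prior),
            class = "summary.ncii_gibbs")
}

#' @export
print.summary.ncii_gibbs <- function(x, digits = 4, ...) {
  cat("Posterior summary (mode and HPD interval per parameter):\n")
  print(round(x$table, digits))
  invisible(x)
}

#' @export
as.matrix.ncii_gibbs <- function(x, ...) x$draws
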