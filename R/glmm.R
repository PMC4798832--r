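#' Logistic mixed models by Laplace approximation
#'
#' Binomial-logit mixed model for binary outcomes (embryo survival) with
#' the same crossed random-intercept vocabulary as [ncii_lmm()].
#' Estimation maximizes the Laplace approximation to the marginal
#' likelihood: an inner penalized iteratively reweighted least squares
#' (PIRLS) loop finds the joint mode of fixed and random effects given the
#' variance components, and a bounded quasi-Newton outer loop optimizes
#' the log variance components. Degenerate responses (all survive / all
#' die) and separation by a fixed effect are flagged and returned with
#' finite (capped) estimates rather than raised as errors.
#'
#' @param formula Mixed formula with a binary (0/1 or logical) response,
#'   e.g. `survived ~ analysis_group + (1|sire) + (1|dam) + (1|sire:dam)`.
#' @param data Data frame.
#' @param boundary_tol Variance estimates below this value are reported as
#'   0 and flagged.
#' @param eta_cap Cap on the absolute linear predictor inside PIRLS,
#'   bounding estimates under separation.
#' @return An object of class `"ncii_glmm"` with `beta`, `se_beta`,
#'   `vcov_beta`, `sigma2`, `loglik` (Laplace), `converged`,
#'   `boundary_terms`, `separation` flag, `n_obs`.
#' @export
ncii_glmm <- function(formula, data, boundary_tol = 1e-6, eta_cap = 15) {
  mats <- build_mixed_matrices(formula, data)
  y <- mats$y
  if (!all(y %in% c(0, 1))) {
    stop("response must be binary (0/1 or logical)", call. = FALSE)
  }
  X <- mats$X
  Zs <- mats$Zs
  q <- length(Zs)
  if (q == 0L) stop("no random terms; use glm() instead", call. = FALSE)
  Z <- do.call(cbind, Zs)
  W <- cbind(X, Z)
  n <- length(y)
  p <- ncol(X)
  m <- ncol(Z)
  m_k <- vapply(Zs, ncol, integer(1))
  term_of_col <- rep(seq_len(q), m_k)

  pirls <- function(s2, return_fit = FALSE) {
    dinv <- c(rep(0, p), 1 / s2[term_of_col])  # 0 = flat prior on beta
    th <- rep(0, p + m)
    dev_old <- Inf
    M <- NULL
    for (it in 1:100) {
      eta <- pmin(pmax(as.numeric(W %*% th), -eta_cap), eta_cap)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      zz <- eta + (y - mu) / w
      M <- crossprod(W, w * W)
      diag(M) <- diag(M) + dinv + 1e-10
      R <- chol(M)
      th_new <- backsolve(R, backsolve(R, crossprod(W, w * zz),
                                       transpose = TRUE))
      mu_c <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
      u <- th_new[(p + 1):(p + m)]
      dev <- -2 * sum(y * log(mu_c) + (1 - y) * log(1 - mu_c)) +
        sum(u^2 * dinv[(p + 1):(p + m)])
      if (max(abs(th_new - th)) < 1e-9 || abs(dev - dev_old) < 1e-10) {
        th <- th_new
        break
      }
      th <- th_new
      dev_old <- dev
    }
    eta <- pmin(pmax(as.numeric(W %*% th), -eta_cap), eta_cap)
    mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
    w <- pmax(mu * (1 - mu), 1e-10)
    u <- th[(p + 1):(p + m)]
    # log|I_m + G^{1/2} Z'WZ G^{1/2}| for the Laplace correction
    sg <- sqrt(s2[term_of_col])
    K <- (sg %o% sg) * crossprod(Z, w * Z)
    diag(K) <- diag(K) + 1
    ldet <- 2 * sum(log(diag(chol(K))))
    lap_dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu)) +
      sum(u^2 / s2[term_of_col]) + ldet
    if (!return_fit) return(lap_dev)
    list(dev = lap_dev, th = th, mu = mu, w = w)
  }

  opt <- stats::nlminb(
    start = rep(log(0.1), q),
    objective = function(ls2) {
      v <- pirls(exp(ls2))
      if (!is.finite(v)) 1e10 else v
    },
    lower = rep(log(1e-8), q), upper = rep(log(1e4), q),
    control = list(rel.tol = 1e-9, iter.max = 300L)
  )
  s2 <- exp(opt$par)
  fitv <- pirls(s2, return_fit = TRUE)
  beta <- fitv$th[seq_len(p)]
  names(beta) <- colnames(X)
  # covariance of beta from the profiled penalized information
  M <- crossprod(W, fitv$w * W)
  diag(M) <- diag(M) + c(rep(0, p), 1 / s2[term_of_col]) + 1e-10
  Minv <- chol2inv(chol(M))
  vcov_beta <- Minv[seq_len(p), seq_len(p), drop = FALSE]
  names(s2) <- mats$labels
  boundary <- names(s2)[s2 <= 1e-8 * 1.0001 | s2 < boundary_tol]
  s2[s2 < boundary_tol] <- 0
  separation <- any(abs(beta) > eta_cap - 1e-6) ||
    max(abs(fitv$th[seq_len(p)])) > 10
  structure(list(
    call = match.call(), formula = formula,
    fixed_formula = mats$fixed_formula,
    beta = beta, se_beta = sqrt(diag(vcov_beta)), vcov_beta = vcov_beta,
    sigma2 = s2, loglik = -fitv$dev / 2, deviance = fitv$dev,
    n_obs = n, n_levels = m_k,
    converged = opt$convergence == 0 ||
      grepl("singular convergence", opt$message %||% ""),
    boundary_terms = boundary,
    separation = separation,
    random_labels = mats$labels,
    y = y, X = X, Zs = Zs, frame = mats$frame,
    u = fitv$th[(p + 1):(p + m)],
    optimizer = opt
  ), class = "ncii_glmm")
}

#' @export
print.ncii_glmm <- function(x, digits = 4, ...) {
  cat(sprintf("Logistic mixed model (Laplace), n = %d\n", x$n_obs))
  cat("  formula: ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  Laplace log-likelihood: %.4f\n", x$loglik))
  cat("Variance components (logit scale):\n")
  print(round(x$sigma2, digits))
  if (length(x$boundary_terms)) {
    cat("  at boundary (0):", paste(x$boundary_terms, collapse = ", "), "\n")
  }
  if (x$separation) {
    cat("  WARNING: (quasi-)separation or degenerate response; estimates capped\n")
  }
  cat("Fixed effects:\n")
  print(round(x$beta, digits))
  invisible(x)
}

#' @export
coef.ncii_glmm <- function(object, ...) object$beta

#' @export
vcov.ncii_glmm <- function(object, ...) object$vcov_beta

#' @export
logLik.ncii_glmm <- function(object, ...) {
  structure(object$loglik,
            df = length(object$beta) + length(object$sigma2),
            nobs = object$n_obs, class = "logLik")
}

#' @export
varcomp.ncii_glmm <- function(object, ...) object$sigma2
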