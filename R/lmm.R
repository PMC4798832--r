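# Gaussian linear mixed models with crossed scalar variance components.
#
# The (restricted) likelihood is profiled analytically over the fixed
# effects and the residual variance, leaving a bounded search over the
# log variance ratios gamma_k = sigma2_k / sigma2_e. With
# V* = I + sum_k gamma_k Z_k Z_k', all quantities reduce via the Woodbury
# identity to operations on the m x m matrix
# K = I_m + G^{1/2} Z'Z G^{1/2}, so a fit precomputes the cross-products
# X'X, X'y, Z'X, Z'y, Z'Z once and each likelihood evaluation costs one
# Cholesky of K.

# Split an lme4-style formula into a fixed-effects formula and the list of
# (1 | g) random intercept terms. Only intercept terms are supported; a
# grouping expression may be an interaction a:b:c.
split_bars <- function(formula) {
  if (length(formula) != 3L) stop("formula needs a response", call. = FALSE)
  bars <- list()
  strip <- function(e) {
    if (is.call(e)) {
      if (identical(e[[1L]], as.name("(")) && is.call(e[[2L]]) &&
          identical(e[[2L]][[1L]], as.name("|"))) {
        bars[[length(bars) + 1L]] <<- e[[2L]]
        return(NULL)
      }
      if (identical(e[[1L]], as.name("+"))) {
        l <- strip(e[[2L]])
        r <- strip(e[[3L]])
        if (is.null(l)) return(r)
        if (is.null(r)) return(l)
        return(call("+", l, r))
      }
    }
    e
  }
  fixed_rhs <- strip(formula[[3L]])
  if (is.null(fixed_rhs)) fixed_rhs <- 1
  fixed <- formula
  fixed[[3L]] <- fixed_rhs
  for (b in bars) {
    if (!identical(b[[2L]], 1) && !identical(b[[2L]], 1L)) {
      stop("only random intercept terms (1 | g) are supported; got (",
           deparse(b[[2L]]), " | ...)", call. = FALSE)
    }
  }
  list(fixed = fixed, bars = lapply(bars, `[[`, 3L))
}

# Build response, fixed design and random-effect indicator matrices from a
# mixed formula, dropping rows with missing values in any used variable.
build_mixed_matrices <- function(formula, data) {
  parts <- split_bars(formula)
  bar_vars <- unique(unlist(lapply(parts$bars, all.vars)))
  fixed_vars <- all.vars(parts$fixed)
  use <- unique(c(fixed_vars, bar_vars))
  miss <- setdiff(use, names(data))
  if (length(miss)) {
    stop("variables not found in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keep <- stats::complete.cases(data[use])
  d <- data[keep, use, drop = FALSE]
  mf <- stats::model.frame(parts$fixed, d)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.numeric(y)
  if (!is.numeric(y)) stop("response must be numeric", call. = FALSE)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("fixed-effects design is singular; collinear column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  labels <- vapply(parts$bars, function(e) paste(all.vars(e), collapse = ":"),
                   character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate random terms: ",
         paste(labels[duplicated(labels)], collapse = ", "), call. = FALSE)
  }
  Zs <- list()
  facs <- list()
  for (i in seq_along(parts$bars)) {
    vars <- all.vars(parts$bars[[i]])
    f <- interaction(d[vars], drop = TRUE, sep = ":", lex.order = FALSE)
    if (nlevels(f) < 2L) {
      stop("random grouping factor '", labels[i],
           "' has fewer than 2 levels", call. = FALSE)
    }
    Zk <- stats::model.matrix(~ 0 + f)
    colnames(Zk) <- paste(labels[i], levels(f), sep = ".")
    Zs[[labels[i]]] <- Zk
    facs[[labels[i]]] <- f
  }
  list(y = as.numeric(y), X = X, Zs = Zs, facs = facs, labels = labels,
       fixed_formula = parts$fixed, frame = d, kept = which(keep))
}

# Precompute the cross-products the profiled likelihood needs.
lmm_precompute <- function(y, X, Zs) {
  Z <- do.call(cbind, Zs)
  m_k <- vapply(Zs, ncol, integer(1))
  list(
    n = length(y), p = ncol(X), m = ncol(Z), q = length(Zs),
    m_k = m_k, term_of_col = rep(seq_along(Zs), m_k),
    XtX = crossprod(X), Xty = crossprod(X, y), yty = sum(y * y),
    ZtX = crossprod(Z, X), Zty = crossprod(Z, y), ZtZ = crossprod(Z)
  )
}

# Minus twice the profiled (restricted) log-likelihood at variance ratios
# gamma (one per random term). Returns the criterion with beta, residual
# variance etc. as attributes when `full = TRUE`.
lmm_objective <- function(gamma, pre, REML, full = FALSE) {
  sg <- sqrt(gamma[pre$term_of_col])
  K <- (sg %o% sg) * pre$ZtZ
  diag(K) <- diag(K) + 1
  R <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(R)) return(1e10)
  W1 <- backsolve(R, sg * pre$ZtX, transpose = TRUE)
  w2 <- backsolve(R, sg * pre$Zty, transpose = TRUE)
  XtVX <- pre$XtX - crossprod(W1)
  XtVy <- pre$Xty - crossprod(W1, w2)
  yVy <- pre$yty - sum(w2 * w2)
  Rx <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(Rx)) return(1e10)
  beta <- backsolve(Rx, backsolve(Rx, XtVy, transpose = TRUE))
  rss <- max(yVy - sum(XtVy * beta), 1e-300)
  logdetV <- 2 * sum(log(diag(R)))
  n <- pre$n
  p <- pre$p
  crit <- if (REML) {
    s2 <- rss / (n - p)
    (n - p) * (log(2 * pi * s2) + 1) + logdetV + 2 * sum(log(diag(Rx)))
  } else {
    s2 <- rss / n
    n * (log(2 * pi * s2) + 1) + logdetV
  }
  if (!is.finite(crit)) return(1e10)
  if (full) {
    cov_beta <- chol2inv(Rx) * s2
    attributes(crit) <- list(beta = as.numeric(beta), sigma2_resid = s2,
                             cov_beta = cov_beta)
  }
  crit
}

#' Linear mixed models for crossed breeding designs
#'
#' Fits a Gaussian linear mixed model with independent scalar variance
#' components for crossed random intercept terms, the structure of a North
#' Carolina II analysis (`sire`, `dam`, `sire:dam`, and optionally
#' group-crossed terms such as `sire:analysis_group` for reaction-norm
#' tests). Estimation maximizes the restricted (default) or full
#' likelihood, profiled analytically over the fixed effects and the
#' residual variance; the remaining search is a deterministic bounded
#' quasi-Newton run over log variance ratios starting from an equal
#' partition of the response variance. Variance estimates optimized to the
#' lower boundary are reported as 0 and flagged.
#'
#' @param formula Model formula with lme4-style random intercept terms,
#'   e.g. `hatch_dd ~ analysis_group + (1|sire) + (1|dam) + (1|sire:dam)`.
#'   Only `(1 | g)` terms are supported; `g` may be an interaction.
#' @param data Data frame; rows with missing values in any used variable
#'   are dropped.
#' @param REML Use restricted maximum likelihood (`TRUE`, default) or full
#'   maximum likelihood (`FALSE`).
#' @param n_starts Number of deterministic optimizer starts (the first at
#'   equal variance partition, later ones at fixed offsets); the best
#'   optimum is kept.
#' @param boundary_tol Variance estimates below
#'   `boundary_tol * var(response)` are reported as exactly 0 and listed
#'   in `boundary_terms`.
#' @return An object of class `"ncii_lmm"` with components `beta`,
#'   `se_beta`, `vcov_beta`, `sigma2` (named per random term),
#'   `sigma2_resid`, `loglik`, `n_obs`, `converged`, `boundary_terms`,
#'   `REML`, plus the design matrices needed by methods.
#' @seealso [anova_ncii()] for the balanced method-of-moments oracle,
#'   [lrt()] for likelihood-ratio tests, [pairwise_contrasts()],
#'   [decompose_variance()].
#' @export
ncii_lmm <- function(formula, data, REML = TRUE, n_starts = 1L,
                     boundary_tol = 1e-8) {
  mats <- build_mixed_matrices(formula, data)
  if (length(mats$Zs) == 0L) {
    stop("no random terms; use lm() for purely fixed models", call. = FALSE)
  }
  pre <- lmm_precompute(mats$y, mats$X, mats$Zs)
  if (pre$n < pre$p + pre$q + 2L) {
    stop("too few complete rows for the requested model", call. = FALSE)
  }
  q <- pre$q
  lower <- rep(-30, q)
  upper <- rep(30, q)
  starts <- list(rep(0, q))
  if (n_starts > 1L) {
    offs <- c(-4, 4, -8, 8)
    for (i in seq_len(min(n_starts - 1L, length(offs)))) {
      starts[[i + 1L]] <- rep(offs[i], q)
    }
  }
  obj <- function(lg) lmm_objective(exp(lg), pre, REML)
  best <- NULL
  for (st in starts) {
    opt <- stats::nlminb(
      start = st, objective = obj, lower = lower, upper = upper,
      control = list(rel.tol = 1e-10, x.tol = 1e-10, iter.max = 500L)
    )
    if (opt$convergence != 0 &&
        !grepl("singular convergence", opt$message %||% "")) {
      # polish with a derivative-free pass, then re-run the bounded search
      nm <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 500L, reltol = 1e-12))
      opt2 <- stats::nlminb(
        start = pmin(pmax(nm$par, lower), upper), objective = obj,
        lower = lower, upper = upper,
        control = list(rel.tol = 1e-10, x.tol = 1e-10, iter.max = 500L)
      )
      if (opt2$objective <= opt$objective) opt <- opt2
    }
    if (is.null(best) || opt$objective < best$objective - 1e-9) best <- opt
  }
  # collapse plateau terms onto the boundary: zeroing a ratio is accepted
  # whenever it costs less than 1e-6 in the criterion
  par <- best$par
  f0 <- best$objective
  for (k in order(par)) {
    if (par[k] <= lower[1] + 1e-8) next
    trial <- par
    trial[k] <- lower[1]
    ft <- obj(trial)
    if (ft <= f0 + 1e-6) {
      par <- trial
      f0 <- min(ft, f0)
    }
  }
  best$par <- par
  gamma <- exp(par)
  crit <- lmm_objective(gamma, pre, REML, full = TRUE)
  at <- attributes(crit)
  s2e <- at$sigma2_resid
  sigma2 <- gamma * s2e
  names(sigma2) <- mats$labels
  vy <- stats::var(mats$y)
  boundary <- names(sigma2)[sigma2 < boundary_tol * vy]
  sigma2[sigma2 < boundary_tol * vy] <- 0
  beta <- at$beta
  names(beta) <- colnames(mats$X)
  se <- sqrt(diag(at$cov_beta))
  names(se) <- names(beta)
  fit <- structure(list(
    call = match.call(),
    formula = formula,
    fixed_formula = mats$fixed_formula,
    REML = REML,
    beta = beta,
    se_beta = se,
    vcov_beta = at$cov_beta,
    sigma2 = sigma2,
    sigma2_resid = s2e,
    loglik = -as.numeric(crit) / 2,
    deviance = as.numeric(crit),
    n_obs = pre$n,
    n_levels = pre$m_k,
    converged = best$convergence == 0 ||
      grepl("singular convergence|false convergence",
            best$message %||% ""),
    boundary_terms = boundary,
    random_labels = mats$labels,
    y = mats$y,
    X = mats$X,
    Zs = mats$Zs,
    facs = mats$facs,
    frame = mats$frame,
    optimizer = list(par = best$par, objective = best$objective,
                     convergence = best$convergence,
                     message = best$message)
  ), class = "ncii_lmm")
  if (!fit$converged) {
    warning("ncii_lmm did not converge; inspect $optimizer", call. = FALSE)
  }
  fit
}

#' @export
print.ncii_lmm <- function(x, digits = 4, ...) {
  cat(sprintf("Linear mixed model (%s), n = %d\n",
              if (x$REML) "REML" else "ML", x$n_obs))
  cat("  formula: ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  log-%slikelihood: %.4f\n",
              if (x$REML) "restricted-" else "", x$loglik))
  cat("Variance components:\n")
  vc <- c(x$sigma2, residual = x$sigma2_resid)
  print(round(vc, digits))
  if (length(x$boundary_terms)) {
    cat("  at boundary (0):", paste(x$boundary_terms, collapse = ", "), "\n")
  }
  cat("Fixed effects:\n")
  print(round(x$beta, digits))
  invisible(x)
}

#' @export
summary.ncii_lmm <- function(object, ...) {
  z <- object$beta / object$se_beta
  coefs <- cbind(Estimate = object$beta, `Std. Error` = object$se_beta,
                 `z value` = z,
                 `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(fit = object, coefficients = coefs,
              varcomp = c(object$sigma2, residual = object$sigma2_resid))
  class(out) <- "summary.ncii_lmm"
  out
}

#' @export
print.summary.ncii_lmm <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nCoefficient table:\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  invisible(x)
}

#' @export
coef.ncii_lmm <- function(object, ...) object$beta

#' @export
vcov.ncii_lmm <- function(object, ...) object$vcov_beta

#' @export
logLik.ncii_lmm <- function(object, ...) {
  structure(object$loglik,
            df = length(object$beta) + length(object$sigma2) + 1L,
            nobs = object$n_obs, REML = object$REML, class = "logLik")
}

#' Extract variance components
#'
#' @param object A fitted `ncii_lmm`, `ncii_glmm` or `ncii_gibbs` summary
#'   source.
#' @param ... Unused.
#' @return Named numeric vector of variance components including the
#'   residual variance (Gaussian models).
#' @export
varcomp <- function(object, ...) UseMethod("varcomp")

#' @export
varcomp.ncii_lmm <- function(object, ...) {
  c(object$sigma2, residual = object$sigma2_resid)
}

#' @export
fitted.ncii_lmm <- function(object, ...) {
  as.numeric(object$X %*% object$beta)
}

#' @export
residuals.ncii_lmm <- function(object, ...) {
  object$y - fitted(object)
}

#' @export
predict.ncii_lmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  tt <- stats::delete.response(stats::terms(object$fixed_formula))
  mf <- stats::model.frame(tt, newdata,
                           xlev = stats::.getXlevels(tt, object$frame))
  X <- stats::model.matrix(tt, mf)
  as.numeric(X %*% object$beta[colnames(X)])
}

#' Simulate responses from a fitted mixed model
#'
#' Draws new responses from the fitted generative model: fresh random
#' effects at the estimated variance components plus Gaussian residuals,
#' on the rows used in fitting.
#'
#' @param object A fitted [ncii_lmm()] model.
#' @param nsim Number of simulated response vectors.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of simulated responses.
#' @export
simulate.ncii_lmm <- function(object, nsim = 1, seed = 1L, ...) {
  mu <- fitted(object)
  n <- length(mu)
  with_seed(seed, {
    sims <- replicate(nsim, {
      y <- mu
      for (k in seq_along(object$Zs)) {
        u <- stats::rnorm(ncol(object$Zs[[k]]), 0,
                          sqrt(object$sigma2[[k]]))
        y <- y + as.numeric(object$Zs[[k]] %*% u)
      }
      y + stats::rnorm(n, 0, sqrt(object$sigma2_resid))
    })
    as.data.frame(sims)
  })
}
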