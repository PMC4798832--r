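# Internal helpers shared across the package.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so package functions never perturb the
# global random sequence.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Symmetric matrix square root with a PSD check; tolerates tiny negative
# eigenvalues from floating point, errors on genuinely indefinite input.
psd_sqrt <- function(R, label = "correlation matrix") {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1)) {
    stop(label, " is not positive semidefinite", call. = FALSE)
  }
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

# Exchangeable (compound-symmetry) correlation matrix.
exch_corr <- function(g, rho) {
  R <- matrix(rho, g, g)
  diag(R) <- 1
  R
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable hash of an R object (used to stamp result tables with the
# generating configuration). Serializes to a temp file and md5-sums it.
config_hash <- function(x) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf), add = TRUE)
  saveRDS(x, tf, version = 2)
  unname(tools::md5sum(tf))
}
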