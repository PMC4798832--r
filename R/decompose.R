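#' Variance decomposition for the NC II design
#'
#' Converts the raw variance components of a sire/dam/sire-by-dam mixed
#' model into the genetic parameters of the full-factorial design:
#' additive genetic variance `V_A = 4 * sigma2_sire` (paternal half-sibs
#' share a quarter of V_A), dam variance `V_Dam = sigma2_dam` (maternal
#' environmental plus genetic effects, not separable here), nonadditive
#' (dominance) variance `V_NA = 4 * sigma2_sire_dam`, residual variance
#' `V_Res = sigma2_e`, total phenotypic variance `V_P` as the sum of the
#' four raw components, and narrow-sense heritability `h2 = V_A / V_P`.
#' Because `V_A` inflates a raw component fourfold while `V_P` sums the
#' raw components, sampling noise can push `h2` above 1. `V_Res` still
#' contains `1/2 V_A` and `3/4 V_NA` in expectation; the returned
#' annotation records this caveat.
#'
#' @param x A fitted [ncii_lmm()] model, or a named numeric vector with
#'   elements `sire`, `dam`, `sire_dam` (or `sire:dam`) and `resid`.
#' @param sire,dam,sire_dam Names of the random terms in the fit holding
#'   the sire, dam and sire-by-dam components.
#' @param ... Unused.
#' @return An object of class `"ncii_varcomp"`: a list with `V_A`,
#'   `V_Dam`, `V_NA`, `V_Res`, `V_P`, `h2`, the raw `sigma2` vector and
#'   an `annotation` string.
#' @examples
#' decompose_variance(c(sire = 0.25, dam = 0.25, sire_dam = 0, resid = 0.5))
#' @export
decompose_variance <- function(x, ...) UseMethod("decompose_variance")

decompose_core <- function(s_s, s_d, s_sd, s_e) {
  if (any(c(s_s, s_d, s_sd, s_e) < 0)) {
    stop("variance components must be >= 0", call. = FALSE)
  }
  V_A <- 4 * s_s
  V_NA <- 4 * s_sd
  V_P <- s_s + s_d + s_sd + s_e
  h2 <- ifelse(V_P > 0, V_A / V_P, 0)
  list(V_A = V_A, V_Dam = s_d, V_NA = V_NA, V_Res = s_e, V_P = V_P, h2 = h2)
}

#' @export
decompose_variance.numeric <- function(x, ...) {
  nm <- names(x)
  pick <- function(keys) {
    j <- which(nm %in% keys)
    if (length(j) != 1L) {
      stop("missing or ambiguous variance component: ",
           paste(keys, collapse = "/"), call. = FALSE)
    }
    x[[j]]
  }
  core <- decompose_core(pick(c("sire", "sire_id")),
                         pick(c("dam", "dam_id")),
                         pick(c("sire_dam", "sire:dam", "sire_id:dam_id")),
                         pick(c("resid", "residual")))
  structure(c(core, list(
    sigma2 = x,
    annotation = paste("V_Res includes environmental variance plus, in",
                       "expectation, 1/2 V_A and 3/4 V_NA; V_P sums the",
                       "raw sire, dam, sire x dam and residual components.")
  )), class = "ncii_varcomp")
}

#' @export
decompose_variance.ncii_lmm <- function(x, sire = "sire_id", dam = "dam_id",
                                        sire_dam = "sire_id:dam_id", ...) {
  s2 <- x$sigma2
  for (term in c(sire, dam, sire_dam)) {
    if (!term %in% names(s2)) {
      stop("fit lacks random term: ", term, call. = FALSE)
    }
  }
  v <- c(sire = unname(s2[[sire]]), dam = unname(s2[[dam]]),
         sire_dam = unname(s2[[sire_dam]]), resid = x$sigma2_resid)
  decompose_variance(v)
}

#' @export
print.ncii_varcomp <- function(x, digits = 4, ...) {
  cat("NC II variance decomposition\n")
  v <- c(V_A = x$V_A, V_Dam = x$V_Dam, V_NA = x$V_NA, V_Res = x$V_Res,
         V_P = x$V_P, h2 = x$h2)
  print(round(v, digits))
  cat("note:", x$annotation, "\n")
  invisible(x)
}

#' Draw-wise variance decomposition of a posterior chain
#'
#' Applies the NC II decomposition to every retained draw of a Gibbs
#' chain, yielding posterior samples of `V_A`, `V_Dam`, `V_NA`, `V_Res`,
#' `V_P` and `h2` from which highest-posterior-density intervals and
#' posterior modes can be computed. The `h2` draws may exceed 1, as the
#' additive variance is four times a raw component.
#'
#' @param chain A [ncii_gibbs()] chain (or a matrix of draws with columns
#'   for the sire, dam, sire-by-dam and residual variances).
#' @param sire,dam,sire_dam,resid Column names of the four components.
#' @return A data frame with one row per retained draw and columns `V_A`,
#'   `V_Dam`, `V_NA`, `V_Res`, `V_P`, `h2`.
#' @export
decompose_posterior <- function(chain, sire = "sire_id", dam = "dam_id",
                                sire_dam = "sire_id:dam_id",
                                resid = "residual") {
  draws <- if (inherits(chain, "ncii_gibbs")) chain$draws else as.matrix(chain)
  if (nrow(draws) == 0L) stop("empty chain", call. = FALSE)
  need <- c(sire, dam, sire_dam, resid)
  miss <- setdiff(need, colnames(draws))
  if (length(miss)) {
    stop("chain lacks component column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  core <- decompose_core(draws[, sire], draws[, dam], draws[, sire_dam],
                         draws[, resid])
  data.frame(core)
}
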