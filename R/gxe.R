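# Genotype-by-environment analysis: paternal sibgroup means,
# cross-environment genetic correlations, and random slope-intercept
# likelihood-ratio tests for interaction variance components.

# Resolve a trait name to a numeric vector, handling the log transform of
# yolk volume ("log_yolk_vol" -> log(yolk_vol_mm3)).
trait_values <- function(records, trait) {
  if (trait %in% names(records)) return(records[[trait]])
  if (trait == "log_yolk_vol") {
    v <- records$yolk_vol_mm3
    if (!is.null(v)) return(log(v))
  }
  stop("trait not found in records: ", trait, call. = FALSE)
}

#' Paternal sibgroup means across environments
#'
#' Mean trait value over all surviving, measured offspring of each sire in
#' each analysis group. These sire-by-environment means are the basis of
#' the family-mean estimate of cross-environment genetic correlations.
#'
#' @param records Embryo-record data frame.
#' @param trait Trait name: a records column, or `"log_yolk_vol"` for the
#'   log-transformed yolk volume.
#' @return A matrix of class `"sire_means"` (sires x analysis groups,
#'   `NA` where a sire has no measured offspring in a group) with the
#'   per-cell offspring counts in `attr(, "counts")` and the trait name in
#'   `attr(, "trait")`.
#' @export
sire_means <- function(records, trait) {
  y <- trait_values(records, trait)
  ok <- !is.na(y)
  sires <- sort(unique(records$sire_id))
  ord <- silver_treatments()$analysis_groups
  groups <- unique(records$analysis_group)
  groups <- c(intersect(ord, groups), setdiff(groups, ord))
  M <- matrix(NA_real_, length(sires), length(groups),
              dimnames = list(sires, groups))
  Nc <- matrix(0L, length(sires), length(groups),
               dimnames = list(sires, groups))
  agg <- tapply(y[ok], list(records$sire_id[ok], records$analysis_group[ok]),
                mean)
  cnt <- tapply(y[ok], list(records$sire_id[ok], records$analysis_group[ok]),
                length)
  M[rownames(agg), colnames(agg)] <- agg
  cnt[is.na(cnt)] <- 0L
  Nc[rownames(cnt), colnames(cnt)] <- cnt
  attr(M, "counts") <- Nc
  attr(M, "trait") <- trait
  class(M) <- c("sire_means", "matrix")
  M
}

#' Cross-environment genetic correlations from sire means
#'
#' Pairwise-complete Pearson correlations of paternal sibgroup means
#' between every pair of analysis groups, with two-sided p-values from the
#' t transform on `n - 2` degrees of freedom and a Bonferroni-adjusted
#' alpha of `0.05 / choose(g, 2)`. With 7 analysis groups this gives 21
#' pairs and a threshold of 0.05/21 = 0.00238 (0.002 at three decimals).
#' The family-mean correlation is attenuated toward zero by within-family
#' sampling noise, so it is a conservative estimate of the underlying
#' genetic correlation.
#'
#' @param means A [sire_means()] matrix.
#' @param alpha Family-wise error level before Bonferroni division.
#' @param min_pairs Minimum complete sire pairs required per group pair;
#'   pairs with fewer yield `NA` with a warning.
#' @return A list of class `"ncii_gcor"`: `corr` (g x g symmetric, unit
#'   diagonal), `p` (raw two-sided p-values), `n` (complete pairs),
#'   `n_pairs`, `bonferroni_alpha`, `significant` (logical matrix,
#'   `raw p < bonferroni_alpha`), `trait`.
#' @export
cross_env_correlation <- function(means, alpha = 0.05, min_pairs = 3L) {
  M <- unclass(means)
  g <- ncol(M)
  groups <- colnames(M)
  corr <- matrix(NA_real_, g, g, dimnames = list(groups, groups))
  pmat <- matrix(NA_real_, g, g, dimnames = list(groups, groups))
  nmat <- matrix(0L, g, g, dimnames = list(groups, groups))
  diag(corr) <- 1
  for (i in seq_len(g - 1L)) {
    for (j in (i + 1L):g) {
      ok <- stats::complete.cases(M[, c(i, j)])
      nij <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- nij
      if (nij < min_pairs) {
        warning(sprintf("fewer than %d complete sire pairs for %s vs %s",
                        min_pairs, groups[i], groups[j]), call. = FALSE)
        next
      }
      r <- stats::cor(M[ok, i], M[ok, j])
      corr[i, j] <- corr[j, i] <- r
      if (nij > 2 && abs(r) < 1) {
        tstat <- r * sqrt(nij - 2) / sqrt(1 - r^2)
        pmat[i, j] <- pmat[j, i] <- 2 * stats::pt(-abs(tstat), nij - 2)
      } else if (abs(r) >= 1) {
        pmat[i, j] <- pmat[j, i] <- 0
      }
    }
  }
  n_pairs <- g * (g - 1L) / 2L
  bonf <- alpha / n_pairs
  structure(list(
    corr = corr, p = pmat, n = nmat, n_pairs = n_pairs,
    bonferroni_alpha = bonf,
    significant = !is.na(pmat) & pmat < bonf,
    trait = attr(means, "trait")
  ), class = "ncii_gcor")
}

#' @export
print.ncii_gcor <- function(x, digits = 2, ...) {
  cat(sprintf(
    "Cross-environment sire-mean correlations (%s): %d pairs, Bonferroni alpha = %.3f\n",
    x$trait %||% "trait", x$n_pairs, x$bonferroni_alpha))
  up <- x$corr
  up[lower.tri(up, diag = TRUE)] <- NA
  mark <- ifelse(x$significant & upper.tri(up), "*", "")
  disp <- matrix(paste0(ifelse(is.na(up), "", formatC(up, digits = digits,
                                                      format = "f")), mark),
                 nrow(up), dimnames = dimnames(up))
  disp[lower.tri(disp, diag = TRUE)] <- "-"
  print(disp, quote = FALSE)
  cat("* raw p below the Bonferroni-adjusted alpha\n")
  invisible(x)
}

#' Random slope-intercept interaction tests for one treatment comparison
#'
#' On the two-group subset (pooled control plus one silver treatment),
#' compares the base random-effects model `(1|sire) + (1|dam) +
#' (1|sire:dam)` against the model adding one group-crossed interaction
#' term — `sire:analysis_group`, `dam:analysis_group` or
#' `sire:dam:analysis_group` — by REML likelihood-ratio test. A
#' significant sire-by-treatment term is additive genetic variance for the
#' reaction norm; the interaction terms are modeled as independent
#' scalar-variance intercept deviations per genotype-by-group cell.
#'
#' @param records Embryo-record data frame.
#' @param trait Trait name (see [sire_means()] for `"log_yolk_vol"`).
#' @param control_group,test_group The two analysis groups compared.
#' @param hatch_covariate Include centered hatching time as a fixed
#'   covariate (used for the size traits).
#' @return A data frame of class `"ncii_gxe_lrt"`: one row per
#'   interaction term with `term`, `chi2`, `df`, `p_value`, `p_boundary`.
#' @export
interaction_lrt_suite <- function(records, trait, control_group = "control",
                                  test_group, hatch_covariate = FALSE) {
  sub <- records[records$analysis_group %in% c(control_group, test_group), ,
                 drop = FALSE]
  if (length(unique(sub$analysis_group)) < 2L) {
    stop("subset must contain both analysis groups", call. = FALSE)
  }
  sub$.y <- trait_values(sub, trait)
  sub <- sub[!is.na(sub$.y), , drop = FALSE]
  fixed <- if (hatch_covariate) ".y ~ analysis_group + hatch_dd"
           else ".y ~ analysis_group"
  base_f <- stats::as.formula(paste(
    fixed, "+ (1|sire_id) + (1|dam_id) + (1|sire_id:dam_id)"))
  base <- ncii_lmm(base_f, sub, REML = TRUE)
  terms <- c(sire_x_treatment = "(1|sire_id:analysis_group)",
             dam_x_treatment = "(1|dam_id:analysis_group)",
             sire_x_dam_x_treatment = "(1|sire_id:dam_id:analysis_group)")
  rows <- lapply(names(terms), function(nm) {
    full_f <- stats::as.formula(paste(
      paste(deparse(base_f), collapse = " "), "+", terms[[nm]]))
    full <- ncii_lmm(full_f, sub, REML = TRUE)
    tst <- lrt(full, base)
    data.frame(term = nm, chi2 = tst$chi2, df = tst$df,
               p_value = tst$p_value, p_boundary = tst$p_boundary,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$trait <- trait
  out$comparison <- paste(control_group, "vs", test_group)
  class(out) <- c("ncii_gxe_lrt", "data.frame")
  out
}
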