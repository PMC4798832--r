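#' Analysis configuration
#'
#' Assembles the configuration of the end-to-end NC II analysis: where the
#' records come from (simulation or a CSV file), the generative parameters
#' for simulation, the chain settings of the Bayesian stage, and the
#' global seed that makes every emitted number reproducible.
#'
#' @param mode `"simulate"` (default) or `"load"`.
#' @param path CSV path of embryo records when `mode = "load"`.
#' @param params [sim_params()] used when simulating.
#' @param design Parent counts and replicate range for simulation.
#' @param chains Gibbs settings for the Bayesian stage (`n_iter`,
#'   `burn_in`, `thin`).
#' @param gibbs Run the Bayesian stage? (It dominates run time.)
#' @param contrast_nsim Monte Carlo draws for contrast adjustment.
#' @param seed Global integer seed; stage seeds are derived from it.
#' @param verbose Log stage progress to standard error.
#' @return A list of class `"ncii_config"`.
#' @export
ncii_config <- function(mode = c("simulate", "load"), path = NULL,
                        params = sim_params(),
                        design = list(n_dams = 4, n_sires = 12,
                                      reps_min = 5, reps_max = 7),
                        chains = list(n_iter = 20000L, burn_in = 2000L,
                                      thin = 10L),
                        gibbs = TRUE, contrast_nsim = 1e5,
                        seed = 1L, verbose = TRUE) {
  mode <- match.arg(mode)
  if (mode == "load" && (is.null(path) || !nzchar(path))) {
    stop("mode = 'load' requires a path", call. = FALSE)
  }
  structure(list(mode = mode, path = path, params = params, design = design,
                 chains = chains, gibbs = gibbs,
                 contrast_nsim = contrast_nsim, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "ncii_config")
}

#' Load an analysis configuration from YAML
#'
#' Reads a YAML file whose keys mirror the [ncii_config()] arguments;
#' trait parameter overrides under `params` are applied on top of the
#' package defaults.
#'
#' @param file YAML file path.
#' @return A `"ncii_config"` object.
#' @export
read_config <- function(file) {
  raw <- yaml::read_yaml(file)
  params <- sim_params()
  if (!is.null(raw$params)) {
    for (tn in intersect(names(raw$params), names(params$traits))) {
      ov <- raw$params[[tn]]
      tp <- params$traits[[tn]]
      if (!is.null(ov$mean)) tp$mean <- ov$mean
      if (!is.null(ov$effects)) tp$effects <- unlist(ov$effects)
      if (!is.null(ov$sigma2)) tp$sigma2 <- unlist(ov$sigma2)[names(tp$sigma2)]
      if (!is.null(ov$r_g)) tp$r_g <- ov$r_g
      if (!is.null(ov$slope_hatch)) tp$slope_hatch <- ov$slope_hatch
      params$traits[[tn]] <- tp
    }
    for (fn in c("p_mort", "measurement_fraction")) {
      if (!is.null(raw$params[[fn]])) params[[fn]] <- raw$params[[fn]]
    }
    validate_sim_params(params)
  }
  args <- list(params = params)
  for (fn in c("mode", "path", "design", "chains", "gibbs",
               "contrast_nsim", "seed", "verbose")) {
    if (!is.null(raw[[fn]])) args[[fn]] <- raw[[fn]]
  }
  do.call(ncii_config, args)
}

#' Per-group trait means and standard errors
#'
#' @param records Embryo-record data frame.
#' @param trait Trait name (see [sire_means()] for `"log_yolk_vol"`).
#' @return Data frame with `analysis_group`, `n`, `mean`, `se` (SE is
#'   `sd/sqrt(n)`; groups with no measured value yield an `NA` row with a
#'   warning).
#' @export
summarize_treatment_means <- function(records, trait) {
  y <- trait_values(records, trait)
  ord <- silver_treatments()$analysis_groups
  groups <- unique(records$analysis_group)
  groups <- c(intersect(ord, groups), setdiff(groups, ord))
  rows <- lapply(groups, function(g) {
    v <- y[records$analysis_group == g & !is.na(y)]
    if (length(v) == 0L) {
      warning("no measured values in group ", g, call. = FALSE)
      return(data.frame(analysis_group = g, n = 0L, mean = NA_real_,
                        se = NA_real_))
    }
    data.frame(analysis_group = g, n = length(v), mean = mean(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0)
  })
  do.call(rbind, rows)
}

#' Mortality summary
#'
#' @param records Embryo-record data frame.
#' @return List with `deaths`, `total`, `percent` (rounded to one
#'   decimal, as conventionally reported).
#' @examples
#' # 15 deaths among 2896 embryos -> 0.5%
#' @export
mortality_summary <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no records", call. = FALSE)
  }
  deaths <- sum(!records$survived)
  total <- nrow(records)
  list(deaths = deaths, total = total,
       percent = round(100 * deaths / total, 1))
}

#' Run the full NC II analysis pipeline
#'
#' Orchestrates the complete analysis: obtain records (simulate or load),
#' validate and pool controls, mortality summary and logistic mixed model
#' with a treatment likelihood-ratio test, per-trait treatment models with
#' multiplicity-adjusted contrasts (ML LRTs for fixed effects), 21
#' per-treatment variance models (3 traits x 7 analysis groups) with REML
#' variance decompositions and random-effect LRT ladders, optional Gibbs
#' chains giving HPD intervals, posterior modes, DIC and
#' Heidelberger-Welch diagnostics, interaction (reaction-norm) LRT suites
#' comparing the control to each silver treatment, and cross-environment
#' sire-mean correlations with Bonferroni correction. Every stage is
#' deterministic given the configuration seed.
#'
#' @param config A [ncii_config()] object.
#' @param out_dir Optional directory; result tables are written there as
#'   CSV with a metadata file, and partial outputs gain an `INCOMPLETE`
#'   marker if a stage fails.
#' @return A list of class `"ncii_results"` with elements `records`,
#'   `treatment_means`, `mortality`, `treatment_tests`, `contrasts`,
#'   `variance_components`, `bayes` (if enabled), `gxe_lrt`,
#'   `correlations`, and `metadata` (seed, config hash, versions,
#'   timestamp).
#' @export
run_full_analysis <- function(config = ncii_config(), out_dir = NULL) {
  stopifnot(inherits(config, "ncii_config"))
  res <- list()
  log_msg <- function(...) {
    if (config$verbose) message(sprintf("[ncii] %s", sprintf(...)))
  }
  stage <- function(name, expr) {
    log_msg("stage: %s", name)
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        try(export_results(res, out_dir), silent = TRUE)
        try(writeLines(sprintf("stage '%s' failed: %s", name,
                               conditionMessage(e)),
                       file.path(out_dir, "INCOMPLETE")), silent = TRUE)
      }
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  seed <- config$seed
  traits <- c("hatch_dd", "length_mm", "log_yolk_vol")
  size_trait <- c(hatch_dd = FALSE, length_mm = TRUE, log_yolk_vol = TRUE)

  records <- stage("data", {
    if (config$mode == "simulate") {
      d <- config$design
      simulate_ncii(d$n_dams, d$n_sires, d$reps_min, d$reps_max,
                    params = config$params, seed = seed)
    } else {
      read_records(config$path)
    }
  })
  res$records <- records

  res$treatment_means <- stage("treatment_means", {
    out <- lapply(traits, function(tr) {
      tab <- summarize_treatment_means(records, tr)
      tab$trait <- tr
      tab
    })
    do.call(rbind, out)
  })

  res$mortality <- stage("mortality", {
    summ <- mortality_summary(records)
    glmm_fit <- ncii_glmm(
      survived ~ analysis_group + (1|sire_id) + (1|dam_id) +
        (1|sire_id:dam_id), records)
    glmm_null <- ncii_glmm(
      survived ~ 1 + (1|sire_id) + (1|dam_id) + (1|sire_id:dam_id),
      records)
    summ$treatment_lrt <- lrt(glmm_fit, glmm_null)
    summ$fit <- glmm_fit
    summ
  })

  res$treatment_tests <- stage("treatment_tests", {
    rows <- list()
    res$contrasts <- list()
    for (tr in traits) {
      d <- records
      d$.y <- trait_values(d, tr)
      fixed_full <- if (size_trait[[tr]]) ".y ~ analysis_group + hatch_dd"
                    else ".y ~ analysis_group"
      fixed_null <- if (size_trait[[tr]]) ".y ~ hatch_dd" else ".y ~ 1"
      rand <- "+ (1|sire_id) + (1|dam_id) + (1|sire_id:dam_id)"
      full_ml <- ncii_lmm(stats::as.formula(paste(fixed_full, rand)), d,
                          REML = FALSE)
      null_ml <- ncii_lmm(stats::as.formula(paste(fixed_null, rand)), d,
                          REML = FALSE)
      tst <- lrt(full_ml, null_ml)
      rows[[tr]] <- data.frame(trait = tr, term = "analysis_group",
                               chi2 = tst$chi2, df = tst$df,
                               p_value = tst$p_value)
      if (size_trait[[tr]]) {
        no_cov <- ncii_lmm(stats::as.formula(paste(
          ".y ~ analysis_group", rand)), d, REML = FALSE)
        tst2 <- lrt(full_ml, no_cov)
        rows[[paste0(tr, "_cov")]] <- data.frame(
          trait = tr, term = "hatch_dd", chi2 = tst2$chi2, df = tst2$df,
          p_value = tst2$p_value)
      }
      full_reml <- ncii_lmm(stats::as.formula(paste(fixed_full, rand)), d,
                            REML = TRUE)
      res$contrasts[[tr]] <- pairwise_contrasts(
        full_reml, "analysis_group", nsim = config$contrast_nsim,
        seed = seed + 17L)
    }
    do.call(rbind, rows)
  })

  res$variance_components <- stage("variance_components", {
    groups <- silver_treatments()$analysis_groups
    groups <- intersect(groups, unique(records$analysis_group))
    rows <- list()
    for (tr in traits) {
      for (g in groups) {
        d <- records[records$analysis_group == g, , drop = FALSE]
        d$.y <- trait_values(d, tr)
        fixed <- if (size_trait[[tr]]) ".y ~ hatch_dd" else ".y ~ 1"
        f3 <- function(terms) stats::as.formula(paste(
          fixed, "+", paste(terms, collapse = " + ")))
        full <- ncii_lmm(f3(c("(1|sire_id)", "(1|dam_id)",
                              "(1|sire_id:dam_id)")), d)
        ref <- ncii_lmm(f3(c("(1|sire_id)", "(1|dam_id)")), d)
        no_sire <- ncii_lmm(f3(c("(1|dam_id)")), d)
        no_dam <- ncii_lmm(f3(c("(1|sire_id)")), d)
        t_sd <- lrt(full, ref)
        t_s <- lrt(ref, no_sire)
        t_d <- lrt(ref, no_dam)
        dec <- decompose_variance(full)
        rows[[paste(tr, g)]] <- data.frame(
          trait = tr, analysis_group = g, n = full$n_obs,
          sigma2_sire = full$sigma2[["sire_id"]],
          sigma2_dam = full$sigma2[["dam_id"]],
          sigma2_sire_dam = full$sigma2[["sire_id:dam_id"]],
          sigma2_resid = full$sigma2_resid,
          V_A = dec$V_A, V_Dam = dec$V_Dam, V_NA = dec$V_NA,
          V_Res = dec$V_Res, V_P = dec$V_P, h2 = dec$h2,
          chi2_sire = t_s$chi2, p_sire = t_s$p_value,
          chi2_dam = t_d$chi2, p_dam = t_d$p_value,
          chi2_sire_dam = t_sd$chi2, p_sire_dam = t_sd$p_value)
      }
    }
    do.call(rbind, rows)
  })

  if (config$gibbs) {
    res$bayes <- stage("bayes", {
      groups <- intersect(silver_treatments()$analysis_groups,
                          unique(records$analysis_group))
      cs <- config$chains
      rows <- list()
      hw_rows <- list()
      ix <- 0L
      for (tr in traits) {
        for (g in groups) {
          ix <- ix + 1L
          d <- records[records$analysis_group == g, , drop = FALSE]
          d$.y <- trait_values(d, tr)
          fixed <- if (size_trait[[tr]]) ".y ~ hatch_dd" else ".y ~ 1"
          ch <- ncii_gibbs(
            stats::as.formula(paste(
              fixed, "+ (1|sire_id) + (1|dam_id) + (1|sire_id:dam_id)")),
            d, n_iter = cs$n_iter, burn_in = cs$burn_in, thin = cs$thin,
            seed = seed + 100L + ix)
          dp <- decompose_posterior(ch)
          summ1 <- function(v) {
            h <- hpd_interval(v)
            c(mode = posterior_mode(v), lower95 = h$lower,
              upper95 = h$upper)
          }
          per <- vapply(dp[c("V_A", "V_Dam", "V_NA", "V_Res", "h2")],
                        summ1, numeric(3))
          rows[[ix]] <- data.frame(
            trait = tr, analysis_group = g,
            component = colnames(per),
            mode = per["mode", ], lower95 = per["lower95", ],
            upper95 = per["upper95", ],
            dic = dic(ch)$dic, row.names = NULL)
          hw_rows[[ix]] <- do.call(rbind, lapply(
            c("sire_id", "dam_id", "sire_id:dam_id", "residual"),
            function(pn) {
              hwd <- heidelberger_welch(ch$draws[, pn])
              data.frame(trait = tr, analysis_group = g, parameter = pn,
                         stationarity = hwd$stationarity_passed,
                         fraction_discarded = hwd$fraction_discarded,
                         halfwidth = hwd$halfwidth_passed)
            }))
        }
      }
      list(summary = do.call(rbind, rows),
           heidelberger_welch = do.call(rbind, hw_rows))
    })
  }

  res$gxe_lrt <- stage("gxe_interactions", {
    groups <- setdiff(intersect(silver_treatments()$analysis_groups,
                                unique(records$analysis_group)),
                      "control")
    rows <- list()
    for (tr in traits) {
      for (g in groups) {
        rows[[paste(tr, g)]] <- interaction_lrt_suite(
          records, tr, control_group = "control", test_group = g,
          hatch_covariate = size_trait[[tr]])
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  res$correlations <- stage("correlations", {
    lapply(stats::setNames(traits, traits), function(tr) {
      cross_env_correlation(sire_means(records, tr))
    })
  })

  res$metadata <- list(
    seed = seed,
    config_hash = config_hash(config[setdiff(names(config), "verbose")]),
    package_version = as.character(utils::packageVersion("ncii")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  class(res) <- "ncii_results"
  if (!is.null(out_dir)) export_results(res, out_dir)
  res
}

#' @export
print.ncii_results <- function(x, ...) {
  cat("NC II analysis results\n")
  cat(sprintf("  records: %d embryos, %d families\n", nrow(x$records),
              length(unique(paste(x$records$sire_id, x$records$dam_id)))))
  if (!is.null(x$mortality)) {
    cat(sprintf("  mortality: %d/%d (%.1f%%)\n", x$mortality$deaths,
                x$mortality$total, x$mortality$percent))
  }
  cat(sprintf("  variance models: %d\n",
              if (is.null(x$variance_components)) 0L
              else nrow(x$variance_components)))
  cat(sprintf("  seed: %s, config hash: %s\n", x$metadata$seed,
              x$metadata$config_hash))
  invisible(x)
}

#' Export result tables as delimited text
#'
#' Writes each tabular element of a result bundle to `dir` as CSV plus a
#' YAML metadata file carrying the seed and configuration hash.
#'
#' @param results A (possibly partial) [run_full_analysis()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(tab, name) {
    utils::write.csv(tab, file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE, na = "")
  }
  if (!is.null(results$records)) wr(results$records, "records")
  if (!is.null(results$treatment_means)) {
    wr(results$treatment_means, "treatment_means")
  }
  if (!is.null(results$treatment_tests)) {
    wr(results$treatment_tests, "treatment_tests")
  }
  if (!is.null(results$contrasts)) {
    for (tr in names(results$contrasts)) {
      wr(as.data.frame(results$contrasts[[tr]]),
         paste0("contrasts_", tr))
    }
  }
  if (!is.null(results$variance_components)) {
    wr(results$variance_components, "variance_components")
  }
  if (!is.null(results$bayes)) {
    wr(results$bayes$summary, "bayes_summary")
    wr(results$bayes$heidelberger_welch, "heidelberger_welch")
  }
  if (!is.null(results$gxe_lrt)) wr(results$gxe_lrt, "gxe_lrt")
  if (!is.null(results$correlations)) {
    for (tr in names(results$correlations)) {
      wr(as.data.frame(results$correlations[[tr]]$corr),
         paste0("correlations_", tr))
    }
  }
  if (!is.null(results$metadata)) {
    yaml::write_yaml(results$metadata, file.path(dir, "run_metadata.yaml"))
  }
  invisible(dir)
}
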