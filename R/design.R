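#' Full-factorial (North Carolina II) cross design
#'
#' Constructs the family list of a North Carolina II breeding design in
#' which every sire is mated to every dam. The motivating experiment
#' crossed 4 dams with 12 sires, yielding 48 full-sib families.
#'
#' @param n_dams Number of dams (females), a positive integer.
#' @param n_sires Number of sires (males), a positive integer.
#' @return An object of class `"ncii_design"`: a list with `dam_ids`,
#'   `sire_ids` and `families`, a data frame holding every sire-by-dam
#'   combination exactly once, ordered dams-outer / sires-inner.
#' @examples
#' d <- ncii_design(4, 12)
#' nrow(d$families)  # 48
#' @export
ncii_design <- function(n_dams, n_sires) {
  if (length(n_dams) != 1L || length(n_sires) != 1L ||
      !is.finite(n_dams) || !is.finite(n_sires) ||
      n_dams < 1 || n_sires < 1 ||
      n_dams != round(n_dams) || n_sires != round(n_sires)) {
    stop("n_dams and n_sires must be positive integers", call. = FALSE)
  }
  dam_ids <- sprintf("D%02d", seq_len(n_dams))
  sire_ids <- sprintf("S%02d", seq_len(n_sires))
  families <- data.frame(
    sire_id = rep(sire_ids, times = n_dams),
    dam_id = rep(dam_ids, each = n_sires),
    stringsAsFactors = FALSE
  )
  structure(
    list(dam_ids = dam_ids, sire_ids = sire_ids, families = families),
    class = "ncii_design"
  )
}

#' @export
print.ncii_design <- function(x, ...) {
  cat(sprintf(
    "NC II full-factorial design: %d dams x %d sires = %d full-sib families\n",
    length(x$dam_ids), length(x$sire_ids), nrow(x$families)
  ))
  invisible(x)
}

#' Silver-exposure treatment scheme
#'
#' The raw treatment structure of the motivating experiment: an untreated
#' control, two sodium-citrate dispersant controls, and silver as ions
#' (AgNO3) or as 20 nm / 100 nm nanoparticles (AgNP20, AgNP100), each at a
#' low (0.5 ug/L) or high (100 ug/L) dose. For analysis the untreated and
#' both citrate controls are pooled into a single control group, giving 7
#' analysis groups.
#'
#' @return A list of class `"ncii_treatments"` with `raw_groups` (9
#'   labels), `analysis_groups` (7 labels, control first), `pooling_map`
#'   (named character vector raw -> analysis) and `dose_levels` (ug/L).
#' @examples
#' sc <- silver_treatments()
#' table(sc$pooling_map)
#' @export
silver_treatments <- function() {
  raw <- c("control_untreated", "citrate_low", "citrate_high",
           "AgNO3_low", "AgNO3_high",
           "AgNP20_low", "AgNP20_high",
           "AgNP100_low", "AgNP100_high")
  analysis <- c("control",
                "AgNO3_low", "AgNO3_high",
                "AgNP20_low", "AgNP20_high",
                "AgNP100_low", "AgNP100_high")
  pooling <- c(control_untreated = "control",
               citrate_low = "control",
               citrate_high = "control",
               AgNO3_low = "AgNO3_low", AgNO3_high = "AgNO3_high",
               AgNP20_low = "AgNP20_low", AgNP20_high = "AgNP20_high",
               AgNP100_low = "AgNP100_low", AgNP100_high = "AgNP100_high")
  structure(
    list(raw_groups = raw, analysis_groups = analysis,
         pooling_map = pooling, dose_levels = c(low = 0.5, high = 100)),
    class = "ncii_treatments"
  )
}

#' Allocate embryos to families, treatment groups and replicates
#'
#' Expands a cross design into one row per embryo. Each family-by-raw-group
#' cell receives a replicate count drawn uniformly from
#' `[reps_min, reps_max]` (the experiment used five to seven replicates per
#' full-sib family per treatment, depending on embryo availability).
#'
#' @param design An [ncii_design()] object.
#' @param scheme A treatment scheme, see [silver_treatments()].
#' @param reps_min,reps_max Bounds on replicates per family per raw group.
#' @param seed Integer seed; the allocation is reproducible given the seed.
#' @return A data frame with one row per embryo: `sire_id`, `dam_id`,
#'   `raw_group`, `analysis_group`, `replicate_index`.
#' @export
allocate_embryos <- function(design, scheme = silver_treatments(),
                             reps_min = 5, reps_max = 7, seed = 1L) {
  if (!inherits(design, "ncii_design") || nrow(design$families) == 0L) {
    stop("'design' must be a non-empty ncii_design", call. = FALSE)
  }
  if (reps_min < 1 || reps_max < reps_min) {
    stop("need 1 <= reps_min <= reps_max", call. = FALSE)
  }
  fams <- design$families
  raw <- scheme$raw_groups
  cells <- expand.grid(fam = seq_len(nrow(fams)), raw_group = raw,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rng <- seq.int(reps_min, reps_max)
  reps <- if (length(rng) == 1L) rep.int(rng, nrow(cells)) else {
    with_seed(seed, sample(rng, nrow(cells), replace = TRUE))
  }
  idx <- rep(seq_len(nrow(cells)), reps)
  out <- data.frame(
    sire_id = fams$sire_id[cells$fam[idx]],
    dam_id = fams$dam_id[cells$fam[idx]],
    raw_group = cells$raw_group[idx],
    stringsAsFactors = FALSE
  )
  out$analysis_group <- unname(scheme$pooling_map[out$raw_group])
  out$replicate_index <- stats::ave(seq_len(nrow(out)),
                                    out$sire_id, out$dam_id, out$raw_group,
                                    FUN = seq_along)
  attr(out, "seed") <- seed
  out
}
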