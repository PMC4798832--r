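# Shared test fixtures, all generated in code.

# Direct balanced NC II generator, independent of the package simulator:
# y = mu + s_i + d_j + (sd)_ij + e, equal replicates per cell.
sim_balanced_ncii <- function(s2 = c(sire = 0.25, dam = 0.25,
                                     sire_dam = 0.1, resid = 0.4),
                              n_sires = 12, n_dams = 4, r = 6,
                              mu = 10, seed = 1) {
  set.seed(seed)
  s <- rnorm(n_sires, 0, sqrt(s2[["sire"]]))
  d <- rnorm(n_dams, 0, sqrt(s2[["dam"]]))
  sd_ <- matrix(rnorm(n_sires * n_dams, 0, sqrt(s2[["sire_dam"]])),
                n_sires, n_dams)
  idx <- expand.grid(sire = seq_len(n_sires), dam = seq_len(n_dams),
                     rep = seq_len(r))
  data.frame(
    sire_id = sprintf("S%02d", idx$sire),
    dam_id = sprintf("D%02d", idx$dam),
    y = mu + s[idx$sire] + d[idx$dam] + sd_[cbind(idx$sire, idx$dam)] +
      rnorm(nrow(idx), 0, sqrt(s2[["resid"]])),
    stringsAsFactors = FALSE
  )
}

# Formula for the standard sire/dam/sire-by-dam model on sim_balanced_ncii.
ncii_formula <- y ~ 1 + (1 | sire_id) + (1 | dam_id) + (1 | sire_id:dam_id)

# Quiet simulator wrapper at reduced scale for fast tests.
quick_records <- function(seed = 1, reps = 2, params = sim_params()) {
  simulate_ncii(reps_min = reps, reps_max = reps, params = params,
                seed = seed)
}

# O(n^2) exhaustive shortest-interval search used as the HPD oracle.
brute_hpd <- function(x, prob) {
  x <- sort(x)
  n <- length(x)
  k <- ceiling(prob * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - k + 1)) {
    for (j in seq.int(i + k - 1, n)) {
      if (x[j] - x[i] < best[2] - best[1]) best <- c(x[i], x[j])
    }
  }
  best
}
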