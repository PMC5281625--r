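# Independent brute-force oracles used to cross-check the implementation.

# Transitive-closure grouping oracle: repeatedly merge any two groups that
# contain a pair within both tolerances, until nothing changes. O(n^3),
# fine for the small random tables it is used on.
oracle_align_groups <- function(mass, rt, mass_tol_ppm, rt_tol_min) {
  n <- length(mass)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        close_mass <- abs(mass[i] - mass[j]) / min(mass[i], mass[j]) * 1e6 <=
          mass_tol_ppm
        close_rt <- abs(rt[i] - rt[j]) <= rt_tol_min
        if (close_mass && close_rt && grp[i] != grp[j]) {
          grp[grp == grp[j]] <- grp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(grp, unique(grp))
}

# same partition up to label permutation?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# random raw-peak table for alignment property tests: a few true features,
# each emitted as several jittered replicate peaks
random_raw_peaks <- function(n_true = 15, samples = c("A", "B"),
                             replicates = 2) {
  mass <- runif(n_true, 100, 800)
  rt <- runif(n_true, 1, 30)
  rows <- list()
  k <- 0
  for (i in seq_len(n_true)) {
    for (s in samples) {
      for (r in seq_len(replicates)) {
        k <- k + 1
        rows[[k]] <- tibble::tibble(
          feature_id = sprintf("P%04d", k),
          neutral_mass = mass[i] * (1 + runif(1, -2, 2) * 1e-6),
          rt = rt[i] + runif(1, -0.05, 0.05),
          ion_mode = "positive",
          sample = s, replicate = r,
          abundance = runif(1, 500, 5000)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

# small hand-buildable feature table
toy_table <- function(masses, rts, abund, samples = c("LC3", "HC3"),
                      replicates = 1, ion_mode = "positive") {
  n <- length(masses)
  feats <- tibble::tibble(
    feature_id = sprintf("F%03d", seq_len(n)),
    neutral_mass = masses, rt = rts,
    ion_mode = rep_len(ion_mode, n)
  )
  ab <- tidyr::expand_grid(
    feature_id = feats$feature_id, sample = samples,
    replicate = seq_len(replicates)
  )
  ab$abundance <- as.vector(t(abund))[
    match(paste(ab$feature_id, ab$sample),
          as.vector(t(outer(feats$feature_id, samples, paste))))]
  feature_table(feats, ab, sample_names = samples,
                replicate_count = replicates)
}

# all chemically valid (integer, non-negative DBE) CHNOPS compositions in a
# bounded box with monoisotopic mass <= mass_max, computed directly from
# the element-count grid (independent of the formula parser)
valid_chnops_grid <- function(c_max = 20, h_max = 30, n_max = 4, o_max = 8,
                              s_max = 2, p_max = 2, mass_max = 500) {
  g <- expand.grid(C = 0:c_max, H = 0:h_max, N = 0:n_max, O = 0:o_max,
                   S = 0:s_max, P = 0:p_max)
  em <- element_masses("monoisotopic")
  g$mass <- g$C * em[["C"]] + g$H * em[["H"]] + g$N * em[["N"]] +
    g$O * em[["O"]] + g$S * em[["S"]] + g$P * em[["P"]]
  dbe <- g$C + 1 + (g$N + g$P) / 2 - g$H / 2
  keep <- rowSums(g[, c("C", "H", "N", "O", "S", "P")]) > 0 &
    g$mass <= mass_max & dbe >= 0 & dbe == floor(dbe)
  g[keep, , drop = FALSE]
}
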