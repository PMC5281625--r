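# Feature alignment, abundance filtering, and shot-noise QC.

# ppm difference between two masses, relative to the smaller
ppm_diff <- function(m1, m2) {
  abs(m1 - m2) / pmin(m1, m2) * 1e6
}

# union-find with path compression
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# single-linkage groups among rows of (mass, rt) under inclusive tolerances;
# returns an integer group id per row
link_groups <- function(mass, rt, mass_tol_ppm, rt_tol_min) {
  n <- length(mass)
  if (n == 0L) return(integer(0))
  ord <- order(mass)
  parent <- seq_len(n)
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    for (b in seq((a + 1), n)) {
      j <- ord[b]
      # sorted by mass, so once past the ppm window no later j can match
      if (ppm_diff(mass[i], mass[j]) > mass_tol_ppm) break
      if (abs(rt[i] - rt[j]) <= rt_tol_min) {
        ri <- uf_find(parent, i); rj <- uf_find(parent, j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  match(roots, unique(roots))
}

#' Align raw LC-MS features across replicates, samples and modes
#'
#' Raw single-replicate peaks whose pairwise mass difference is within
#' `mass_tol_ppm` (relative to the smaller mass) and whose retention times
#' differ by at most `rt_tol_min` are merged by single-linkage transitive
#' closure, separately within each ion mode. Merged abundance per
#' (sample, replicate) is the sum of member abundances; merged mass and
#' retention time are abundance-weighted means. Aligned features that then
#' match across the two ionization modes under the same tolerances are
#' counted once: the higher-total-abundance mode's values are kept and the
#' feature is flagged `ion_mode = "both"`.
#'
#' Because grouping is transitive, a chain of pairwise-close peaks can merge
#' members whose extreme masses differ by more than the pairwise tolerance.
#'
#' @param raw_features Tibble of raw peaks: `feature_id`, `neutral_mass`,
#'   `rt`, `ion_mode`, `sample`, `replicate`, `abundance` (one row per
#'   single-replicate peak), as returned by [read_raw_features()].
#' @param mass_tol_ppm Maximum pairwise mass difference, ppm (inclusive).
#' @param rt_tol_min Maximum pairwise retention-time difference, minutes
#'   (inclusive).
#' @param sample_names,replicate_count Optional overrides for the output
#'   table's sample grid.
#' @param dedupe_modes Match aligned features across ion modes and count
#'   dual-mode features once (default TRUE).
#' @return A `feature_table` of aligned features.
#' @export
align_features <- function(raw_features, mass_tol_ppm = 6, rt_tol_min = 0.25,
                           sample_names = NULL, replicate_count = NULL,
                           dedupe_modes = TRUE) {
  raw <- tibble::as_tibble(raw_features)
  if (nrow(raw) == 0L) {
    return(feature_table(
      tibble::tibble(feature_id = character(), neutral_mass = numeric(),
                     rt = numeric(), ion_mode = character()),
      tibble::tibble(feature_id = character(), sample = character(),
                     replicate = integer(), abundance = numeric()),
      sample_names = sample_names %||% character(),
      replicate_count = replicate_count %||% 0L,
      provenance = "align_features"
    ))
  }
  merged <- dplyr::bind_rows(lapply(split(raw, raw$ion_mode), function(sub) {
    grp <- link_groups(sub$neutral_mass, sub$rt, mass_tol_ppm, rt_tol_min)
    sub$group <- grp
    dplyr::group_by(sub, .data$group) |>
      dplyr::summarise(
        neutral_mass = stats::weighted.mean(
          .data$neutral_mass,
          if (sum(.data$abundance) > 0) .data$abundance else rep(1, dplyr::n())),
        rt = stats::weighted.mean(
          .data$rt,
          if (sum(.data$abundance) > 0) .data$abundance else rep(1, dplyr::n())),
        ion_mode = .data$ion_mode[1],
        members = list(.data$feature_id),
        cells = list(data.frame(sample = .data$sample,
                                replicate = .data$replicate,
                                abundance = .data$abundance)),
        total_abundance = sum(.data$abundance),
        .groups = "drop"
      )
  }))
  # cross-mode de-duplication under the same tolerances
  if (dedupe_modes && length(unique(merged$ion_mode)) > 1L) {
    grp <- link_groups(merged$neutral_mass, merged$rt, mass_tol_ppm, rt_tol_min)
    keep <- logical(nrow(merged))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      if (length(unique(merged$ion_mode[idx])) > 1L) {
        win <- idx[which.max(merged$total_abundance[idx])]
        merged$ion_mode[win] <- "both"
        keep[win] <- TRUE
      } else {
        keep[idx] <- TRUE
      }
    }
    merged <- merged[keep, , drop = FALSE]
  }
  merged <- merged[order(merged$neutral_mass, merged$rt), , drop = FALSE]
  merged$feature_id <- sprintf("F%05d", seq_len(nrow(merged)))
  ab <- dplyr::bind_rows(Map(function(id, cells) {
    cells <- dplyr::group_by(cells, .data$sample, .data$replicate) |>
      dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop")
    cells$feature_id <- id
    cells
  }, merged$feature_id, merged$cells))
  feats <- merged[, c("feature_id", "neutral_mass", "rt", "ion_mode", "members")]
  feature_table(
    feats, ab[, c("feature_id", "sample", "replicate", "abundance")],
    sample_names = sample_names %||% unique(raw$sample),
    replicate_count = replicate_count %||% max(raw$replicate),
    provenance = "align_features"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove features below the abundance floor in every sample
#'
#' A feature is removed only if its per-sample mean abundance is strictly
#' below `threshold_iu` in *every* sample; a single sample at or above the
#' floor retains it. Below ~1,000 i.u. the probability of detection drops
#' off sharply, so the default floor removes the unreliable tail.
#'
#' @param table A `feature_table`.
#' @param threshold_iu Abundance floor in instrument units.
#' @return The filtered `feature_table`, with attributes `n_removed` and
#'   `n_retained`.
#' @export
filter_low_abundance <- function(table, threshold_iu = 1000) {
  stopifnot(inherits(table, "feature_table"))
  means <- sample_means(table)
  keep_ids <- unique(means$feature_id[means$mean_abundance >= threshold_iu])
  keep <- table$features$feature_id %in% keep_ids
  out <- feature_table(
    table$features[keep, , drop = FALSE],
    table$abundances[table$abundances$feature_id %in% keep_ids, , drop = FALSE],
    sample_names = table$sample_names,
    replicate_count = table$replicate_count,
    provenance = table$provenance
  )
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Expected relative standard deviation from ion-counting shot noise
#'
#' Instrument abundance units convert to detected ions at `iu_per_ion` i.u.
#' per ion (1,000 i.u. ~ 80 ions at the default 12.5). For a Poisson ion
#' count N the expected RSD of replicate measurements is 1/sqrt(N).
#'
#' @param abundance_iu Abundance in i.u. (> 0, vectorized).
#' @param iu_per_ion Instrument units per detected ion.
#' @return Expected RSD (dimensionless).
#' @export
#' @examples
#' expected_shot_noise_rsd(1000) # ~0.112 (80 ions)
expected_shot_noise_rsd <- function(abundance_iu, iu_per_ion = 12.5) {
  if (any(abundance_iu <= 0)) {
    stop("abundance must be > 0 to define a shot-noise RSD", call. = FALSE)
  }
  1 / sqrt(abundance_iu / iu_per_ion)
}

#' Shot-noise consistency QC of replicate abundances
#'
#' For every (feature, sample) whose mean abundance passes `min_mean_iu`,
#' compares the observed replicate RSD (sd/mean) against the shot-noise
#' expectation; the measurement is consistent when observed RSD <=
#' `tolerance_factor` x expected. On a well-behaved instrument ~90% or more
#' of triplicate measurements are consistent with counting noise alone.
#'
#' @param table A `feature_table` with >= 2 replicates.
#' @param tolerance_factor Multiple of the expected RSD tolerated.
#' @param iu_per_ion Instrument units per detected ion.
#' @param min_mean_iu Only measurements at or above this mean abundance are
#'   assessed.
#' @return A list of class `qc_report`: `measurements` (tibble with
#'   observed/expected RSD and a `consistent` flag per feature x sample)
#'   and `consistent_fraction`.
#' @export
qc_shot_noise <- function(table, tolerance_factor = 2, iu_per_ion = 12.5,
                          min_mean_iu = 1000) {
  stopifnot(inherits(table, "feature_table"))
  if (table$replicate_count < 2L) {
    stop("shot-noise QC needs at least 2 replicates", call. = FALSE)
  }
  meas <- dplyr::summarise(
    dplyr::group_by(table$abundances, .data$feature_id, .data$sample),
    mean_abundance = mean(.data$abundance),
    observed_rsd = stats::sd(.data$abundance) / mean(.data$abundance),
    .groups = "drop"
  )
  meas <- meas[meas$mean_abundance >= min_mean_iu, , drop = FALSE]
  meas$expected_rsd <- expected_shot_noise_rsd(meas$mean_abundance, iu_per_ion)
  meas$consistent <- meas$observed_rsd <= tolerance_factor * meas$expected_rsd
  structure(
    list(
      measurements = meas,
      consistent_fraction = if (nrow(meas)) mean(meas$consistent) else NA_real_,
      tolerance_factor = tolerance_factor,
      iu_per_ion = iu_per_ion
    ),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", nrow(x$measurements), " measurements; ",
      sprintf("%.1f%%", 100 * x$consistent_fraction),
      " consistent with shot noise (<= ", x$tolerance_factor,
      "x expected RSD)\n", sep = "")
  invisible(x)
}
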