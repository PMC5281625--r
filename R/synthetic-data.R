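# Seeded generators for every input the pipeline consumes, with recorded
# ground truth: compound libraries, triplicate two-mode feature tables with
# ion-counting shot noise, retention-time calibration standards, and
# genome-bin communities with configurable pathway content.

#' Configuration for the synthetic-data generators
#'
#' Defaults emulate the study conditions of a two-pipeline (high- vs
#' low-corrosion) pigging-debris comparison: four samples (pig runs 3 and
#' 11 of each pipeline) measured in triplicate in two ESI modes at
#' 12.5 i.u. per detected ion, a compound library with a controlled
#' odd-nitrogen fraction, log-normal true abundances with Poisson
#' ion-counting replicate noise, an alkylsuccinate spike-in series with
#' decoys, and a genome-bin community whose denitrifier and
#' sulfate-reducer fractions mirror the field system (78%/39% of LC3/LC11
#' cells denitrifying; 29%/34% of HC3/HC11 and 1.5%/1.6% of LC3/LC11 cells
#' sulfate-reducing).
#'
#' @param seed Integer seed; fixed seed gives identical outputs.
#' @param samples Sample names.
#' @param system_map Named sample -> system map.
#' @param replicate_count Replicates per sample.
#' @param iu_per_ion Instrument units per detected ion.
#' @param n_library,n_true_metabolites,n_exochemicals Library size, number
#'   of library-derived features, number of unidentifiable background
#'   ("exochemical") features.
#' @param odd_n_fraction Fraction of library compounds with an odd nitrogen
#'   count.
#' @param pathway_free_fraction Fraction of library compounds with no
#'   pathway membership.
#' @param min_separation_ppm Minimum pairwise mass separation enforced
#'   among library/feature masses (keeps annotation unambiguous).
#' @param rt_intercept,rt_coefficients,rt_noise_sd True retention-time
#'   model: minutes, minutes per descriptor unit, and calibration noise.
#' @param n_standards Authentic standards used to calibrate the RT model.
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters of true
#'   feature abundances (i.u.).
#' @param sample_scatter_sdlog Per-sample log-normal scatter around a
#'   feature's base abundance.
#' @param frac_hc_enriched,frac_lc_enriched,enrichment_fold Fractions of
#'   metabolite features enriched in each system, and the fold applied.
#' @param rn_target_percent Named per-sample targets for the true
#'   odd-mass abundance share (RN, percent); odd-parity feature abundances
#'   are rescaled per sample to hit them. The defaults emulate the field
#'   pattern: ~40% in both early pig samples, rising with deposit depth in
#'   the low-corrosion system (55%) and falling in the high-corrosion
#'   system (30%). `NULL` disables the calibration.
#' @param positive_fraction Fraction of features detected in positive mode.
#' @param mass_jitter_ppm Uniform mass perturbation of emitted features.
#' @param spike_n Carbon numbers of the spiked alkylsuccinate series.
#' @param spike_anchors Anchor retention times (data frame `n`, `rt`) for
#'   the spiked series.
#' @param n_decoys Near-mass decoys (8-15 ppm off the spiked series).
#' @param replicate_noise `"poisson"` (shot noise) or `"none"` (replicates
#'   equal the true mean exactly).
#' @param bin_spec Genome-bin community specification; see
#'   [default_bin_spec()].
#' @param total_bases Named per-sample metagenome sizes in bases.
#' @param mean_read_length Mean read length (bases per read).
#' @param coverage_noise_sdlog Multiplicative log-normal noise on bin
#'   coverages (0 = noiseless).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(
    seed = 1L,
    samples = c("LC3", "LC11", "HC3", "HC11"),
    system_map = default_system_map,
    replicate_count = 3L,
    iu_per_ion = 12.5,
    n_library = 400L,
    n_true_metabolites = 250L,
    n_exochemicals = 150L,
    odd_n_fraction = 0.5,
    pathway_free_fraction = 0.3,
    min_separation_ppm = 25,
    rt_intercept = 20,
    rt_coefficients = c(2, -1.5, 1, 0.8, -0.6, 1.2),
    rt_noise_sd = 0.5,
    n_standards = 33L,
    abundance_meanlog = log(8000),
    abundance_sdlog = 1.0,
    sample_scatter_sdlog = 0.3,
    frac_hc_enriched = 0.10,
    frac_lc_enriched = 0.06,
    enrichment_fold = 10,
    rn_target_percent = c(LC3 = 40, LC11 = 55, HC3 = 40, HC11 = 30),
    positive_fraction = 0.72,
    mass_jitter_ppm = 1,
    spike_n = 2:10,
    spike_anchors = data.frame(n = c(6, 10), rt = c(5.98, 12.0)),
    n_decoys = 9L,
    replicate_noise = c("poisson", "none"),
    bin_spec = default_bin_spec(),
    total_bases = c(LC3 = 2.20e9, LC11 = 2.11e9, HC3 = 2.20e9, HC11 = 7.54e8),
    mean_read_length = 250,
    coverage_noise_sdlog = 0.01) {
  replicate_noise <- match.arg(replicate_noise)
  stopifnot(length(rt_coefficients) == 6, seed == as.integer(seed),
            n_true_metabolites <= n_library)
  cfg <- as.list(environment())
  structure(cfg, class = "generator_config")
}

#' Default genome-bin community specification
#'
#' One row per genome bin: identity, site, bin length, carried pathway
#' (`NA` = none) and true per-sample community fractions. The default
#' community mirrors the field system: two denitrifying *Pseudomonas*-like
#' LC bins, sulfate-reducing *Desulfonatronospira*/*Desulfohalobium*-like
#' HC bins, a small LC sulfate-reducer, plus fermentative/methanogenic
#' bins without TEA pathways of interest. Fractions per sample sum to < 1
#' (binning never captures the whole community).
#'
#' @return Tibble with columns `bin_id`, `site`, `total_length_bp`,
#'   `pathway`, `frac_<sample>`.
#' @export
default_bin_spec <- function() {
  tibble::tribble(
    ~bin_id, ~site, ~total_length_bp, ~pathway,
      ~frac_LC3, ~frac_LC11, ~frac_HC3, ~frac_HC11,
    "LC_pseudomonas_1", "LC", 4749114, "denitrification",
      0.48, 0.20, 0, 0,
    "LC_pseudomonas_2", "LC", 4853824, "denitrification",
      0.30, 0.19, 0, 0,
    "LC_desulfonatronospira", "LC", 2136066, "sulfate_reduction",
      0.015, 0.016, 0, 0,
    "LC_methylophaga", "LC", 3244921, NA,
      0.08, 0.18, 0, 0,
    "HC_desulfonatronospira", "HC", 2132562, "sulfate_reduction",
      0, 0, 0.20, 0.22,
    "HC_desulfohalobium", "HC", 2640115, "sulfate_reduction",
      0, 0, 0.09, 0.12,
    "HC_thermococcus", "HC", 2131658, NA,
      0, 0, 0.25, 0.10,
    "HC_methanothermococcus", "HC", 1256481, "methanogenesis",
      0, 0, 0.02, 0.15
  )
}

# sample one chemically plausible CHNOPS formula with the requested
# nitrogen parity; H count chosen so the ring-and-double-bond count is a
# non-negative integer (even-electron molecule)
sample_formula <- function(odd_nitrogen) {
  C <- sample(4:20, 1)
  N <- if (odd_nitrogen) sample(c(1L, 3L), 1, prob = c(0.8, 0.2)) else {
    sample(c(0L, 2L, 4L), 1, prob = c(0.6, 0.3, 0.1))
  }
  O <- sample(0:8, 1)
  S <- rbinom(1, 1, 0.1)
  P <- rbinom(1, 1, 0.05)
  dbe <- sample(0:6, 1)
  H <- 2L * C + 2L + N + P - 2L * dbe
  while (H < 2L) {
    dbe <- dbe - 1L
    H <- 2L * C + 2L + N + P - 2L * dbe
  }
  counts <- c(C = C, H = H, N = N, O = O, S = S, P = P)
  counts <- counts[counts > 0]
  format_formula(structure(as.integer(counts), names = names(counts),
                           class = "molecular_formula"))
}

#' Generate a synthetic compound library
#'
#' Formulas are sampled from plausible CHNOPS compositions with a
#' controlled odd-nitrogen fraction; masses are rejection-sampled to keep
#' every pair separated by at least `min_separation_ppm` so exact-mass
#' annotation has a unique answer. Six descriptors are drawn standard
#' normal and the true retention time follows the configured linear model
#' exactly; a subset of compounds (the authentic standards) carries a
#' reference retention time.
#'
#' @param config A [generator_config()].
#' @return Library tibble compatible with [match_features()], with extra
#'   ground-truth columns `nitrogen_count` and `rt_true`.
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 101L)
  n <- config$n_library
  if (n == 0L) {
    return(tibble::tibble(
      compound_id = character(), name = character(), formula = character(),
      source_db = character(), db_priority = integer(),
      pathway_ids = character(), pathways = list(),
      d1 = numeric(), d2 = numeric(), d3 = numeric(),
      d4 = numeric(), d5 = numeric(), d6 = numeric(),
      reference_rt = numeric(), theoretical_mass = numeric(),
      nitrogen_count = integer(), rt_true = numeric()
    ))
  }
  odd <- runif(n) < config$odd_n_fraction
  formulas <- character(n)
  masses <- numeric(0)
  for (i in seq_len(n)) {
    repeat {
      f <- sample_formula(odd[i])
      m <- monoisotopic_mass(f)
      if (!length(masses) ||
          min(abs(m - masses) / pmin(m, masses) * 1e6) >=
            config$min_separation_ppm) {
        formulas[i] <- f
        masses <- c(masses, m)
        break
      }
    }
  }
  n_count <- vapply(formulas, function(f) {
    counts <- parse_formula(f)
    if ("N" %in% names(counts)) as.integer(counts[["N"]]) else 0L
  }, integer(1))
  D <- matrix(rnorm(6 * n), ncol = 6,
              dimnames = list(NULL, paste0("d", 1:6)))
  rt_true <- config$rt_intercept + drop(D %*% config$rt_coefficients)
  dbs <- sample(names(default_db_priority), n, replace = TRUE,
                prob = c(0.5, 0.2, 0.2, 0.1))
  pool <- c("glycolysis", "tca_cycle", "amino_acid_metabolism",
            "carbohydrate_metabolism", "fatty_acid_biosynthesis",
            "sterol_biosynthesis", "porphyrin_metabolism",
            "taurine_metabolism", "phenylpropanoid_biosynthesis",
            "isoprenoid_biosynthesis", "peptide_turnover",
            "secondary_metabolism")
  pathways <- lapply(seq_len(n), function(i) {
    if (runif(1) < config$pathway_free_fraction) character(0) else {
      sample(pool, sample(1:2, 1))
    }
  })
  standards <- sample(n, min(config$n_standards, n))
  lib <- tibble::tibble(
    compound_id = sprintf("CPD%04d", seq_len(n)),
    name = sprintf("synthetic metabolite %d", seq_len(n)),
    formula = formulas,
    source_db = dbs,
    db_priority = unname(default_db_priority[dbs]),
    pathway_ids = vapply(pathways, paste, character(1), collapse = ";"),
    pathways = pathways
  )
  lib <- dplyr::bind_cols(lib, tibble::as_tibble(D))
  lib$reference_rt <- NA_real_
  lib$reference_rt[standards] <- rt_true[standards]
  lib$theoretical_mass <- masses
  lib$nitrogen_count <- n_count
  lib$rt_true <- rt_true
  lib
}

#' Generate retention-time calibration standards
#'
#' Observed retention times of the library's authentic standards under the
#' true linear model plus Gaussian measurement noise.
#'
#' @param config A [generator_config()].
#' @param library Library from [generate_library()].
#' @return Tibble `d1`..`d6`, `rt`, suitable for [fit_rt_model()].
#' @export
generate_rt_standards <- function(config, library) {
  set.seed(config$seed + 102L)
  std <- library[!is.na(library$reference_rt), , drop = FALSE]
  out <- tibble::as_tibble(as.data.frame(std)[, paste0("d", 1:6)])
  out$rt <- std$rt_true + rnorm(nrow(std), 0, config$rt_noise_sd)
  out
}

#' Generate an aligned feature table with ground truth
#'
#' Emits one aligned feature per selected library metabolite (mass
#' perturbed within `mass_jitter_ppm` of the theoretical value, retention
#' time from the true model), unidentifiable "exochemical" background
#' features whose masses are rejection-sampled to match no library entry
#' within 18 ppm, an alkylsuccinate spike-in series on the configured
#' anchor line, and near-mass decoys 8-15 ppm off the spiked masses.
#' True per-sample abundances are log-normal with system-enrichment
#' effects; replicate measurements are Poisson ion counts scaled by
#' `iu_per_ion` (or exact copies when `replicate_noise = "none"`).
#'
#' @param config A [generator_config()].
#' @param library Library from [generate_library()].
#' @return List: `table` (a `feature_table`), `truth` (list with
#'   `features` tibble carrying kind, true parity and true means,
#'   `rn` per-sample true RN percent, `differential` true enrichment
#'   labels, `spike_ids`, `decoy_ids`), and `spike_series` (the
#'   `homolog_series` with its anchors).
#' @export
generate_feature_tables <- function(config, library) {
  stopifnot(inherits(config, "generator_config"))
  if (nrow(library) == 0L) stop("library is empty", call. = FALSE)
  set.seed(config$seed + 103L)
  samples <- config$samples
  jit <- config$mass_jitter_ppm

  picked <- library[sample(nrow(library), config$n_true_metabolites), ]
  met <- tibble::tibble(
    kind = "metabolite",
    compound_id = picked$compound_id,
    formula = picked$formula,
    nitrogen_count = picked$nitrogen_count,
    true_mass = picked$theoretical_mass,
    neutral_mass = picked$theoretical_mass *
      (1 + runif(nrow(picked), -jit, jit) * 1e-6),
    ion_mode = ifelse(runif(nrow(picked)) < config$positive_fraction,
                      "positive", "negative"),
    rt = pmax(picked$rt_true + rnorm(nrow(picked), 0, 0.05), 0.1)
  )
  met$rt[met$ion_mode == "negative"] <-
    runif(sum(met$ion_mode == "negative"), 1, 40)

  # spiked series defined up front so background masses can avoid it too
  series <- homolog_series("alkylsuccinate", config$spike_n,
                           anchor_rts = config$spike_anchors)
  members <- generate_series(series)

  # exochemical background: masses matching nothing in the library
  exo_mass <- numeric(config$n_exochemicals)
  occupied <- c(library$theoretical_mass, members$theoretical_mass)
  i <- 0L
  while (i < config$n_exochemicals) {
    m <- runif(1, 100, 900)
    if (min(abs(m - occupied) / pmin(m, occupied) * 1e6) >= 18) {
      i <- i + 1L
      exo_mass[i] <- m
      occupied <- c(occupied, m)
    }
  }
  exo <- tibble::tibble(
    kind = "exochemical", compound_id = NA_character_,
    formula = NA_character_, nitrogen_count = NA_integer_,
    true_mass = exo_mass, neutral_mass = exo_mass,
    ion_mode = c("negative", "positive")[
      1L + (runif(length(exo_mass)) < config$positive_fraction)],
    rt = runif(length(exo_mass), 1, 40)
  )

  # alkylsuccinate spike-ins on the anchor line, plus near-mass decoys
  line_rt <- expected_rt(series, members$n)$expected_rt
  spike <- tibble::tibble(
    kind = "spike", compound_id = NA_character_,
    formula = members$formula,
    nitrogen_count = 0L,
    true_mass = members$theoretical_mass,
    neutral_mass = members$theoretical_mass *
      (1 + runif(nrow(members), -0.3, 0.3) * 1e-6),
    ion_mode = "negative",
    rt = pmax(line_rt * (1 + rnorm(nrow(members), 0, 0.01)), 0.1),
    series_n = members$n
  )
  n_dec <- min(config$n_decoys, nrow(members))
  dec_idx <- sample(nrow(members), n_dec)
  decoy <- tibble::tibble(
    kind = "decoy", compound_id = NA_character_,
    formula = NA_character_, nitrogen_count = NA_integer_,
    true_mass = members$theoretical_mass[dec_idx],
    neutral_mass = members$theoretical_mass[dec_idx] *
      (1 + sample(c(-1, 1), n_dec, replace = TRUE) *
         runif(n_dec, 8, 15) * 1e-6),
    ion_mode = "negative",
    rt = pmax(line_rt[dec_idx] * (1 + rnorm(n_dec, 0, 0.01)), 0.1),
    series_n = members$n[dec_idx]
  )

  feats <- dplyr::bind_rows(met, exo, spike, decoy)
  feats$feature_id <- sprintf("F%05d", seq_len(nrow(feats)))

  # true parity: formula nitrogen count when known, nominal-mass rounding
  # for unidentifiable features
  parity <- nitrogen_parity(feats$true_mass)$is_odd
  known <- !is.na(feats$nitrogen_count)
  parity[known] <- feats$nitrogen_count[known] %% 2L == 1L
  feats$true_odd <- parity

  # true per-sample mean abundances
  n_feat <- nrow(feats)
  base <- rlnorm(n_feat, config$abundance_meanlog, config$abundance_sdlog)
  enr <- sample(c("none", "HC", "LC"), n_feat, replace = TRUE,
                prob = c(1 - config$frac_hc_enriched - config$frac_lc_enriched,
                         config$frac_hc_enriched, config$frac_lc_enriched))
  true_means <- matrix(0, n_feat, length(samples),
                       dimnames = list(feats$feature_id, samples))
  for (s in samples) {
    scatter <- rlnorm(n_feat, 0, config$sample_scatter_sdlog)
    fold <- ifelse(enr == unname(config$system_map[s]),
                   config$enrichment_fold, 1)
    true_means[, s] <- base * scatter * fold
  }
  # spikes are prominent in the late high-corrosion sample
  spike_rows <- which(feats$kind == "spike")
  if ("HC11" %in% samples) {
    true_means[spike_rows, "HC11"] <-
      pmax(true_means[spike_rows, "HC11"], 3e4)
  }
  # calibrate per-sample odd-mass abundance shares to the configured RN
  # targets by rescaling the odd-parity features
  if (!is.null(config$rn_target_percent)) {
    for (s in intersect(samples, names(config$rn_target_percent))) {
      tgt <- config$rn_target_percent[[s]]
      if (is.na(tgt)) next
      odd_sum <- sum(true_means[feats$true_odd, s])
      even_sum <- sum(true_means[!feats$true_odd, s])
      if (odd_sum > 0 && even_sum > 0) {
        true_means[feats$true_odd, s] <- true_means[feats$true_odd, s] *
          tgt * even_sum / ((100 - tgt) * odd_sum)
      }
    }
  }
  feats$enriched_in <- ifelse(enr == "none", NA_character_, enr)

  # replicate abundances: Poisson ion counts x iu_per_ion
  ab <- tidyr::expand_grid(
    feature_id = feats$feature_id, sample = samples,
    replicate = seq_len(config$replicate_count)
  )
  mu <- true_means[cbind(ab$feature_id, ab$sample)]
  ab$abundance <- if (config$replicate_noise == "poisson") {
    rpois(nrow(ab), mu / config$iu_per_ion) * config$iu_per_ion
  } else mu

  tab <- feature_table(
    feats[, c("feature_id", "neutral_mass", "rt", "ion_mode")],
    ab, sample_names = samples,
    replicate_count = config$replicate_count,
    provenance = sprintf("generate_feature_tables(seed=%d)", config$seed)
  )

  tm <- true_means
  colnames(tm) <- paste0("true_", samples)
  truth_feats <- dplyr::bind_cols(
    feats[, c("feature_id", "kind", "compound_id", "formula",
              "nitrogen_count", "true_mass", "true_odd", "enriched_in")],
    tibble::as_tibble(tm)
  )
  rn_true <- vapply(samples, function(s) {
    100 * sum(true_means[feats$true_odd, s]) / sum(true_means[, s])
  }, numeric(1))
  sys_true <- vapply(unique(unname(config$system_map[samples])), function(g) {
    rowSums(true_means[, samples[config$system_map[samples] == g],
                       drop = FALSE])
  }, numeric(n_feat))
  true_diff <- differential_features(
    dplyr::bind_cols(tibble::tibble(feature_id = feats$feature_id),
                     tibble::as_tibble(sys_true)),
    systems = colnames(sys_true)
  )
  list(
    table = tab,
    truth = list(
      features = truth_feats,
      rn = setNames(rn_true, samples),
      differential = true_diff,
      spike_ids = feats$feature_id[feats$kind == "spike"],
      decoy_ids = feats$feature_id[feats$kind == "decoy"]
    ),
    spike_series = series
  )
}

#' Generate synthetic metagenome tables with ground truth
#'
#' Builds the genome-bin table, gene-count table and metagenome-size table
#' implied by a bin community specification. Coverage of a bin in a sample
#' is `fraction x total_bases / length` with multiplicative log-normal
#' noise; pathway-positive bins receive one gene from every required group
#' of their pathway's definition, and all bins receive housekeeping genes
#' (plus, occasionally, an incomplete subset of another pathway's genes,
#' which must not trigger a presence call). Gene read counts are Poisson
#' draws consistent with bin abundances.
#'
#' @param config A [generator_config()].
#' @return List: `bins` (tibble compatible with [cell_fraction()]),
#'   `gene_counts` (`gene`, `sample`, `count`), `sizes` (`sample`,
#'   `total_reads`, `total_bases`), and `truth` (per-bin pathway flags and
#'   true per-sample pathway fractions).
#' @export
generate_metagenome_tables <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 104L)
  spec <- config$bin_spec
  samples <- config$samples
  frac_cols <- paste0("frac_", samples)
  stopifnot(all(frac_cols %in% names(spec)))
  fr <- as.matrix(as.data.frame(spec)[, frac_cols])
  colnames(fr) <- samples
  if (any(colSums(fr) > 1)) {
    stop("bin fractions exceed 1 in at least one sample", call. = FALSE)
  }
  defs <- default_pathway_definitions()
  housekeeping <- c("rpoB", "gyrA", "recA", "dnaK", "rplB")

  genes <- lapply(seq_len(nrow(spec)), function(i) {
    g <- housekeeping
    pw <- spec$pathway[i]
    if (!is.na(pw)) {
      g <- c(g, vapply(defs[[pw]], function(group) {
        if (length(group) == 1L) group else sample(group, 1)
      }, character(1)))
    }
    # occasional incomplete marker carry-over (never a full pathway)
    if (is.na(pw) && runif(1) < 0.3) g <- c(g, "dsrA")
    unique(g)
  })

  total_bases <- config$total_bases[samples]
  cov <- fr * 0
  for (s in samples) {
    noise <- if (config$coverage_noise_sdlog > 0) {
      rlnorm(nrow(spec), 0, config$coverage_noise_sdlog)
    } else rep(1, nrow(spec))
    cov[, s] <- fr[, s] * total_bases[[s]] / spec$total_length_bp * noise
  }

  bins <- tibble::tibble(
    bin_id = spec$bin_id,
    site = spec$site,
    contig_count = sample(20:150, nrow(spec), replace = TRUE),
    total_length_bp = spec$total_length_bp,
    gene_annotations = vapply(genes, paste, character(1), collapse = ";"),
    recruitment_label = spec$bin_id,
    genes = genes
  )
  for (s in samples) bins[[paste0("coverage_", s)]] <- cov[, s]

  sizes <- tibble::tibble(
    sample = samples,
    total_reads = round(unname(total_bases) / config$mean_read_length),
    total_bases = unname(total_bases)
  )

  all_genes <- unique(unlist(genes))
  counts <- tidyr::expand_grid(gene = all_genes, sample = samples)
  lambda <- mapply(function(g, s) {
    carriers <- vapply(genes, function(set) g %in% set, logical(1))
    total_reads <- sizes$total_reads[sizes$sample == s]
    sum(fr[carriers, s]) * total_reads * 1e-4
  }, counts$gene, counts$sample)
  counts$count <- rpois(nrow(counts), lambda)

  pw_flags <- vapply(seq_len(nrow(spec)), function(i) spec$pathway[i],
                     character(1))
  true_fracs <- lapply(setdiff(unique(pw_flags), NA), function(pw) {
    idx <- which(pw_flags == pw)
    setNames(100 * colSums(fr[idx, , drop = FALSE]), samples)
  })
  names(true_fracs) <- setdiff(unique(pw_flags), NA)

  list(
    bins = bins,
    gene_counts = counts,
    sizes = sizes,
    truth = list(
      bin_pathway = setNames(pw_flags, spec$bin_id),
      pathway_fraction_percent = true_fracs
    )
  )
}
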