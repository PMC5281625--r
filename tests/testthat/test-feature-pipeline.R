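raw_pair <- function(m1, m2, rt1, rt2, ab1 = 1000, ab2 = 3000) {
  tibble::tibble(
    feature_id = c("a", "b"),
    neutral_mass = c(m1, m2),
    rt = c(rt1, rt2),
    ion_mode = "positive",
    sample = "S1", replicate = c(1L, 1L),
    abundance = c(ab1, ab2)
  )
}

test_that("alignment merges peaks within both tolerances and only then", {
  # 4.0 ppm apart, 0.12 min apart -> one aligned feature
  merged <- align_features(raw_pair(202.1205, 202.1213, 5.98, 6.10))
  expect_equal(n_features(merged), 1L)
  # abundance-weighted mass between the two member masses
  w <- c(1000, 3000) / 4000
  expect_equal(merged$features$neutral_mass,
               sum(c(202.1205, 202.1213) * w), tolerance = 1e-9)
  expect_equal(merged$features$rt, sum(c(5.98, 6.10) * w), tolerance = 1e-9)
  # same masses, RT 0.32 min apart -> separate
  apart <- align_features(raw_pair(202.1205, 202.1213, 5.98, 6.30))
  expect_equal(n_features(apart), 2L)
  # mass difference beyond 6 ppm -> separate
  apart2 <- align_features(raw_pair(202.1205, 202.1220, 5.98, 6.00))
  expect_equal(n_features(apart2), 2L)
})

test_that("alignment handles singleton and empty input", {
  single <- raw_pair(202.1205, 300.0, 5.98, 6.10)[1, ]
  out <- align_features(single)
  expect_equal(n_features(out), 1L)
  expect_equal(out$features$neutral_mass, 202.1205)
  empty <- align_features(single[0, ])
  expect_equal(n_features(empty), 0L)
})

test_that("alignment is idempotent and conserves total abundance", {
  set.seed(101)
  for (i in 1:3) {
    raw <- random_raw_peaks(n_true = 12)
    once <- align_features(raw)
    expect_equal(sum(once$abundances$abundance), sum(raw$abundance))
    # re-feed the aligned features as raw peaks
    realigned_input <- dplyr::left_join(
      once$abundances, once$features[, c("feature_id", "neutral_mass", "rt",
                                         "ion_mode")],
      by = "feature_id"
    )
    twice <- align_features(realigned_input)
    expect_equal(n_features(twice), n_features(once))
    expect_equal(sort(twice$features$neutral_mass),
                 sort(once$features$neutral_mass), tolerance = 1e-9)
  }
})

test_that("alignment grouping matches the brute-force closure oracle", {
  set.seed(202)
  for (i in 1:6) {
    n <- sample(10:50, 1)
    mass <- runif(n, 100, 110) # crowded range to force chance collisions
    rt <- runif(n, 5, 6)
    raw <- tibble::tibble(
      feature_id = sprintf("P%03d", seq_len(n)),
      neutral_mass = mass, rt = rt, ion_mode = "positive",
      sample = "S1", replicate = 1L, abundance = runif(n, 100, 1000)
    )
    out <- align_features(raw, mass_tol_ppm = 50, rt_tol_min = 0.25)
    want <- oracle_align_groups(mass, rt, 50, 0.25)
    expect_equal(n_features(out), length(unique(want)))
    # partition check: members of each aligned feature = an oracle group
    got <- integer(n)
    for (k in seq_len(nrow(out$features))) {
      ids <- out$features$members[[k]]
      got[match(ids, raw$feature_id)] <- k
    }
    expect_true(same_partition(got, want))
  }
})

test_that("dual-mode features are de-duplicated keeping the richer mode", {
  raw <- tibble::tibble(
    feature_id = c("pos1", "neg1"),
    neutral_mass = c(146.0579, 146.0580),
    rt = c(5.0, 5.1),
    ion_mode = c("positive", "negative"),
    sample = "S1", replicate = 1L,
    abundance = c(2000, 9000)
  )
  out <- align_features(raw)
  expect_equal(n_features(out), 1L)
  expect_equal(out$features$ion_mode, "both")
  expect_equal(sum(out$abundances$abundance), 9000) # negative mode kept
  # without de-duplication both survive
  out2 <- align_features(raw, dedupe_modes = FALSE)
  expect_equal(n_features(out2), 2L)
})

test_that("abundance floor removes features below it in every sample only", {
  tab <- toy_table(
    masses = c(100.1, 200.2, 300.3),
    rts = c(1, 2, 3),
    abund = rbind(c(800, 999), c(800, 1200), c(1000, 0)),
    samples = c("S1", "S2")
  )
  out <- filter_low_abundance(tab, 1000)
  expect_equal(attr(out, "n_removed"), 1L)
  expect_equal(attr(out, "n_retained"), 2L)
  # below the floor everywhere -> removed; one sample at/above -> retained
  expect_setequal(out$features$feature_id, c("F002", "F003"))
})

test_that("abundance floor never removes a feature whose max mean passes", {
  set.seed(303)
  for (i in 1:5) {
    n <- 30
    tab <- toy_table(
      masses = sort(runif(n, 100, 900)), rts = runif(n, 1, 30),
      abund = matrix(rlnorm(2 * n, log(1000), 1), ncol = 2),
      samples = c("S1", "S2")
    )
    out <- filter_low_abundance(tab, 1000)
    means <- sample_means(tab)
    maxmean <- tapply(means$mean_abundance, means$feature_id, max)
    expect_setequal(out$features$feature_id, names(maxmean)[maxmean >= 1000])
    expect_equal(attr(out, "n_removed") + attr(out, "n_retained"), n)
  }
})

test_that("expected shot-noise RSD follows 1/sqrt(ion count)", {
  expect_equal(expected_shot_noise_rsd(1000), 1 / sqrt(80))
  expect_equal(expected_shot_noise_rsd(12.5), 1)
  expect_equal(expected_shot_noise_rsd(4000), 1 / sqrt(320))
  expect_error(expected_shot_noise_rsd(0), "> 0")
})

test_that("shot-noise QC flags replicate scatter beyond the expectation", {
  feats <- tibble::tibble(feature_id = c("f1", "f2"),
                          neutral_mass = c(100.1, 200.2),
                          rt = c(1, 2), ion_mode = "positive")
  ab <- tibble::tibble(
    feature_id = rep(c("f1", "f2"), each = 3),
    sample = "S1", replicate = rep(1:3, 2),
    abundance = c(1000, 1000, 1000, 1000, 3000, 5000)
  )
  tab <- feature_table(feats, ab)
  qc <- qc_shot_noise(tab)
  m <- qc$measurements
  expect_true(m$consistent[m$feature_id == "f1"])
  expect_false(m$consistent[m$feature_id == "f2"])
  expect_equal(m$observed_rsd[m$feature_id == "f2"], 2000 / 3000,
               tolerance = 1e-9)
  expect_equal(qc$consistent_fraction, 0.5)
  expect_error(qc_shot_noise(toy_table(100.1, 1, matrix(c(1, 1), 1, 2))),
               "replicates")
})

test_that("Poisson-generated tables pass shot-noise QC", {
  cfg <- generator_config(seed = 5, n_library = 150,
                          n_true_metabolites = 100, n_exochemicals = 60)
  gen <- generate_feature_tables(cfg, generate_library(cfg))
  qc <- qc_shot_noise(gen$table)
  expect_gte(qc$consistent_fraction, 0.9)
})

test_that("feature tables round-trip through delimited text", {
  tab <- toy_table(c(100.1, 200.2), c(1, 2),
                   rbind(c(500, 1500), c(2500, 0)), samples = c("S1", "S2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(back$features$neutral_mass, tab$features$neutral_mass)
  expect_equal(sum(back$abundances$abundance), sum(tab$abundances$abundance))
})

test_that("a noise column gates raw peaks at read time", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(
    feature_id = c("a", "b"), neutral_mass_da = c(100.1, 100.2),
    rt_min = 1, ion_mode = "positive", sample = "S1", replicate = 1L,
    abundance_iu = c(1000, 200), noise_iu = c(100, 100)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  raw <- read_raw_features(path) # default 3x: 200 < 300 is dropped
  expect_equal(raw$feature_id, "a")
  expect_equal(nrow(read_raw_features(path, noise_factor = 1)), 2L)
})
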