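test_that("RN is the odd-mass abundance percentage", {
  # odd nominal mass 147 with abundance 300, even 146 with 700 -> 30%
  tab <- toy_table(c(147.1130, 146.0579), c(1, 2),
                   rbind(c(300, 10), c(700, 10)), samples = c("S1", "S2"))
  rn <- rn_statistic(tab, "S1")
  expect_equal(rn$rn_percent, 30)
  expect_equal(rn$odd_abundance, 300)
  # all even -> 0%
  tab0 <- toy_table(c(146.0579, 174.0892), c(1, 2),
                    rbind(c(300, 10), c(700, 10)), samples = c("S1", "S2"))
  expect_equal(rn_statistic(tab0, "S1")$rn_percent, 0)
  # zero total abundance is undefined
  tabz <- toy_table(146.0579, 1, matrix(0, 1, 2), samples = c("S1", "S2"))
  expect_error(rn_statistic(tabz, "S1"), "undefined")
})

test_that("RN is scale invariant and bounded", {
  set.seed(31)
  masses <- runif(40, 100, 480)
  ab <- matrix(rlnorm(80, 8, 1), 40, 2)
  t1 <- toy_table(masses, runif(40, 1, 30), ab, samples = c("S1", "S2"))
  t2 <- toy_table(masses, runif(40, 1, 30), ab * 37.5, samples = c("S1", "S2"))
  r1 <- rn_statistic(t1, "S1")$rn_percent
  r2 <- rn_statistic(t2, "S1")$rn_percent
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_gte(r1, 0); expect_lte(r1, 100)
})

test_that("an accepted formula overrides mass rounding in RN", {
  # mass rounds to odd 147, but the matched formula has zero nitrogens
  tab <- toy_table(c(146.5002, 150.0), c(1, 1), rbind(c(500, 1), c(500, 1)),
                   samples = c("S1", "S2"))
  lib <- tibble::tibble(compound_id = "C001", formula = "C6H10O4")
  ann <- tibble::tibble(feature_id = "F001", compound_id = "C001",
                        accepted = TRUE)
  plain <- rn_statistic(tab, "S1")
  fixed <- rn_statistic(tab, "S1", annotations = ann, library = lib)
  expect_equal(plain$rn_percent, 50)
  expect_equal(fixed$rn_percent, 0)
})

test_that("system sums add the per-sample means of each system", {
  tab <- toy_table(
    c(100.1, 200.2), c(1, 2),
    rbind(c(100, 200, 0, 50), c(0, 0, 0, 0)),
    samples = c("LC3", "LC11", "HC3", "HC11")
  )
  sys <- system_sums(tab)
  expect_equal(sys$LC[sys$feature_id == "F001"], 300)
  expect_equal(sys$HC[sys$feature_id == "F001"], 50)
  expect_equal(sys$LC[sys$feature_id == "F002"], 0)
  expect_error(system_sums(tab, c(LC3 = "LC")), "not in system map")
  # brute-force oracle on a random table
  set.seed(41)
  ab <- matrix(rlnorm(20, 8, 1), 5, 4)
  tab2 <- toy_table(sort(runif(5, 100, 500)), runif(5, 1, 10), ab,
                    samples = c("LC3", "LC11", "HC3", "HC11"))
  sys2 <- system_sums(tab2)
  expect_equal(sys2$LC, unname(ab[, 1] + ab[, 2]))
  expect_equal(sys2$HC, unname(ab[, 3] + ab[, 4]))
})

test_that("differential features respect both gates and boundaries", {
  sys <- tibble::tibble(
    feature_id = sprintf("F%d", 1:5),
    HC = c(60000, 9000, 50000, 20000, 0),
    LC = c(5000, 1000, 10000, 0, 30000)
  )
  d <- differential_features(sys)
  flags <- d$per_feature$enriched_in
  expect_equal(flags[1], "HC")        # ratio 12, gate passed
  expect_true(is.na(flags[2]))        # abundance gate fails
  expect_equal(flags[3], "HC")        # ratio exactly 5 counts (inclusive)
  expect_equal(flags[4], "HC")        # zero denominator -> infinite ratio
  expect_equal(flags[5], "LC")
  expect_equal(d$hc_enriched_count, 3L)
  expect_equal(d$lc_enriched_count, 1L)
})

test_that("enriched sets are disjoint and shrink as gates tighten", {
  set.seed(51)
  for (i in 1:4) {
    sys <- tibble::tibble(
      feature_id = sprintf("F%03d", 1:200),
      HC = rlnorm(200, 9, 2), LC = rlnorm(200, 9, 2)
    )
    d <- differential_features(sys)
    f <- d$per_feature$enriched_in
    expect_equal(sum(f == "HC", na.rm = TRUE) + sum(f == "LC", na.rm = TRUE),
                 sum(!is.na(f)))
    d_hi_ab <- differential_features(sys, min_abundance = 30000)
    d_hi_ratio <- differential_features(sys, min_ratio = 10)
    expect_lte(d_hi_ab$hc_enriched_count + d_hi_ab$lc_enriched_count,
               d$hc_enriched_count + d$lc_enriched_count)
    expect_lte(d_hi_ratio$hc_enriched_count + d_hi_ratio$lc_enriched_count,
               d$hc_enriched_count + d$lc_enriched_count)
  }
})

test_that("similarity fraction counts two-sided features under the fold", {
  sys <- tibble::tibble(
    feature_id = sprintf("F%d", 1:10),
    HC = c(10, 10, 10, 10, 10, 10, 100, 100, 100, 0),
    LC = c(11, 12, 13, 14, 15, 16, 10, 10, 300, 100)
  )
  r <- ratio_distribution(sys)
  # 6 of 9 two-sided features have max/min < 3 (ratio 30 excluded twice,
  # the 100/300 pair exactly 3 is not < 3)
  expect_equal(r$n_two_sided, 9L)
  expect_equal(r$n_one_sided, 1L)
  expect_equal(r$fraction_similar, 6 / 9)
  ident <- tibble::tibble(feature_id = "F1", HC = 5, LC = 5)
  expect_equal(ratio_distribution(ident)$fraction_similar, 1)
})

test_that("identified ratio among the top-N follows accepted annotations", {
  n <- 300
  tab <- toy_table(sort(runif(n, 100, 900)), runif(n, 1, 30),
                   cbind(seq(1000, by = 10, length.out = n), rep(1, n)),
                   samples = c("S1", "S2"))
  means <- sample_means(tab)
  means <- means[means$sample == "S1", ]
  top <- means$feature_id[order(-means$mean_abundance,
                                means$feature_id)][1:200]
  ann <- tibble::tibble(feature_id = top[1:120], compound_id = "x",
                        accepted = TRUE)
  r <- id_ratio_top_n(tab, ann, "S1", n = 200)
  expect_equal(r$ratio, 1.5) # 120 identified / 80 not
  r0 <- id_ratio_top_n(tab, ann[0, ], "S1", n = 200)
  expect_equal(r0$ratio, 0)
  rall <- id_ratio_top_n(tab, tibble::tibble(feature_id = top,
                                             compound_id = "x",
                                             accepted = TRUE), "S1", n = 200)
  expect_true(is.infinite(rall$ratio))
  expect_true(rall$all_identified)
  expect_error(id_ratio_top_n(tab, ann, "S1", n = 1000), "exceeds")
})

test_that("PCA separates generator-defined system clusters", {
  cfg <- generator_config(seed = 33, n_library = 120,
                          n_true_metabolites = 90, n_exochemicals = 40,
                          frac_hc_enriched = 0.25, frac_lc_enriched = 0.25,
                          enrichment_fold = 30)
  gen <- generate_feature_tables(cfg, generate_library(cfg))
  p <- pca_features(gen$table, scale = "log")
  sysname <- unname(default_system_map[p$scores$sample])
  hc <- p$scores$PC1[sysname == "HC"]
  lc <- p$scores$PC1[sysname == "LC"]
  expect_true(min(hc) > max(lc) || min(lc) > max(hc)) # no overlap on PC1
  # linear and log scaling give closely related leading components
  p_lin <- pca_features(gen$table, scale = "linear")
  expect_gt(abs(cor(p$scores$PC1, p_lin$scores$PC1)), 0.9)
  # explained variance well-formed
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_lte(sum(p$explained_variance), 1 + 1e-9)
})

test_that("identical replicate profiles collapse to coincident scores", {
  feats <- tibble::tibble(feature_id = sprintf("F%d", 1:5),
                          neutral_mass = 100 + 1:5, rt = 1:5,
                          ion_mode = "positive")
  ab <- tidyr::expand_grid(feature_id = feats$feature_id,
                           sample = c("S1", "S2"), replicate = 1:3)
  ab$abundance <- rep(c(2e4, 3e4, 4e4, 5e4, 6e4), each = 6)
  tab <- feature_table(feats, ab)
  p <- pca_features(tab, min_abundance = 10000)
  expect_lt(diff(range(p$scores$PC1)), 1e-8)
  expect_lt(diff(range(p$scores$PC2)), 1e-8)
})
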