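make_library <- function(formulas, priorities = 1L, dbs = "KEGG",
                         descriptors = NULL, reference_rt = NA_real_,
                         pathways = NULL) {
  n <- length(formulas)
  lib <- tibble::tibble(
    compound_id = sprintf("C%03d", seq_len(n)),
    name = sprintf("cpd %d", seq_len(n)),
    formula = formulas,
    source_db = rep_len(dbs, n),
    db_priority = rep_len(as.integer(priorities), n),
    pathway_ids = "",
    pathways = pathways %||% rep(list(character(0)), n),
    reference_rt = rep_len(reference_rt, n)
  )
  if (is.null(descriptors)) {
    descriptors <- matrix(NA_real_, n, 6)
  }
  colnames(descriptors) <- paste0("d", 1:6)
  lib <- dplyr::bind_cols(lib, tibble::as_tibble(descriptors))
  lib$theoretical_mass <- vapply(lib$formula, monoisotopic_mass, numeric(1),
                                 USE.NAMES = FALSE)
  lib
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("noiseless retention-time calibration recovers the model exactly", {
  set.seed(1)
  beta <- c(1.5, -2, 0.5, 3, -1, 0.25)
  D <- matrix(rnorm(6 * 12), ncol = 6, dimnames = list(NULL, paste0("d", 1:6)))
  std <- as.data.frame(D)
  std$rt <- 2 + drop(D %*% beta)
  m <- fit_rt_model(std)
  expect_equal(m$intercept, 2, tolerance = 1e-9)
  expect_equal(m$coefficients, beta, tolerance = 1e-9)
  expect_equal(m$residual_sd, 0, tolerance = 1e-7)
  # predictions reproduce the calibration RTs
  expect_equal(predict_rt(m, std), std$rt, tolerance = 1e-9)
})

test_that("calibration rejects underdetermined or degenerate designs", {
  set.seed(2)
  D <- matrix(rnorm(6 * 6), ncol = 6, dimnames = list(NULL, paste0("d", 1:6)))
  std <- as.data.frame(D); std$rt <- rnorm(6)
  expect_error(fit_rt_model(std), ">= 8 standards")
  D2 <- matrix(rnorm(6 * 12), ncol = 6, dimnames = list(NULL, paste0("d", 1:6)))
  std2 <- as.data.frame(D2)
  std2$d6 <- std2$d5 # collinear
  std2$rt <- rnorm(12)
  expect_error(fit_rt_model(std2), "rank deficient")
})

test_that("predicted retention time is the affine descriptor combination", {
  m <- structure(list(intercept = 2, coefficients = rep(1, 6)),
                 class = "rt_model")
  expect_equal(predict_rt(m, rep(0, 6)), 2)
  expect_equal(predict_rt(m, rep(0.5, 6)), 5)
})

test_that("mass matching gates on ppm and positive-mode RT deviation", {
  lib <- make_library("C6H10O4")
  tab <- toy_table(c(146.0580, 146.0590), c(5, 5),
                   rbind(c(1000, 1000), c(1000, 1000)))
  ann <- match_features(tab, lib, mass_tol_ppm = 6)
  # 0.6 ppm candidate retained, 7.5 ppm not matched
  expect_equal(ann$feature_id, "F001")
  expect_equal(ann$mass_error_ppm,
               (146.0580 - monoisotopic_mass("C6H10O4")) /
                 monoisotopic_mass("C6H10O4") * 1e6)
  expect_true(all(abs(ann$mass_error_ppm) <= 6))

  # RT gate: predicted 5 min, observed 10 min -> deviation 1.0 > 0.45
  lib_rt <- make_library("C6H10O4", descriptors = matrix(0, 1, 6))
  m <- fit_rt_model({
    set.seed(3)
    D <- matrix(rnorm(6 * 10), ncol = 6, dimnames = list(NULL, paste0("d", 1:6)))
    std <- as.data.frame(D); std$rt <- 5 + drop(D %*% rep(0.001, 6)); std
  })
  pos <- toy_table(146.0580, 10.0, matrix(1000, 1, 2))
  expect_equal(nrow(match_features(pos, lib_rt, rt_model = m)), 0L)
  # negative-mode features skip the RT gate
  neg <- toy_table(146.0580, 10.0, matrix(1000, 1, 2), ion_mode = "negative")
  expect_equal(nrow(match_features(neg, lib_rt, rt_model = m)), 1L)
})

test_that("confidence rubric spans 1-10 deterministically", {
  expect_equal(confidence_score(0, 0, 1L), 10L)
  expect_equal(confidence_score(6, 0.45, 4L), 1L)
  # 3 ppm, no RT prediction, top priority: 10 - 1.5 - 1 - 0 -> 7
  expect_equal(confidence_score(3, NA, 1L), 7L)
  # authentic standard match forces 10 regardless of penalties
  expect_equal(confidence_score(5.9, 0.4, 4L, standard_match = TRUE), 10L)
  expect_true(all(confidence_score(runif(50, 0, 6), runif(50, 0, 0.45),
                                   sample(1:6, 50, TRUE)) %in% 1:10))
})

test_that("best-candidate selection is a stable total order", {
  cand <- tibble::tibble(
    feature_id = "F1",
    compound_id = c("Cb", "Ca", "Cc"),
    mass_error_ppm = c(1, 2, 2),
    priority_rank = c(2L, 1L, 1L),
    confidence = c(9L, 9L, 7L)
  )
  # tie on confidence 9 -> lower priority rank wins
  expect_equal(select_best(cand)$compound_id, "Ca")
  for (i in 1:5) {
    perm <- cand[sample(nrow(cand)), ]
    expect_equal(select_best(perm)$compound_id, "Ca")
  }
  expect_null(select_best(cand[0, ]))
  # further tie-break: smaller |ppm|, then compound_id
  tie <- tibble::tibble(
    feature_id = "F1", compound_id = c("Cz", "Ca"),
    mass_error_ppm = c(1, 1), priority_rank = c(1L, 1L),
    confidence = c(8L, 8L)
  )
  expect_equal(select_best(tie)$compound_id, "Ca")
})

test_that("pathway roll-up counts memberships and the unassigned bucket", {
  lib <- make_library(c("C6H10O4", "C7H12O4", "C8H14O4"),
                      pathways = list("P", c("P", "Q"), character(0)))
  ann <- tibble::tibble(
    feature_id = c("F001", "F002", "F003"),
    compound_id = c("C001", "C002", "C003"),
    accepted = TRUE
  )
  pw <- map_pathways(ann, lib)
  expect_equal(pw$n_metabolites[pw$pathway == "P"], 2L)
  expect_equal(pw$n_metabolites[pw$pathway == "Q"], 1L)
  expect_equal(pw$n_metabolites[pw$pathway == "unassigned"], 1L)
  # all pathway-free -> everything unassigned
  lib2 <- make_library(c("C6H10O4", "C7H12O4"))
  pw2 <- map_pathways(ann[1:2, ], lib2)
  expect_equal(pw2$pathway, "unassigned")
  expect_equal(pw2$n_metabolites, 2L)
})

test_that("annotation recall is complete on well-separated synthetic data", {
  cfg <- generator_config(seed = 9, n_library = 120, n_true_metabolites = 80,
                          n_exochemicals = 0)
  lib <- generate_library(cfg)
  gen <- generate_feature_tables(cfg, lib)
  ann <- match_features(gen$table, lib, mass_tol_ppm = 6)
  truth <- gen$truth$features
  met <- truth[truth$kind == "metabolite", ]
  acc <- ann[ann$accepted, ]
  hit <- acc[match(met$feature_id, acc$feature_id), ]
  expect_equal(hit$compound_id, met$compound_id) # 100% recall, right compound
  # shrinking the tolerance never accepts more
  for (tol in c(6, 3, 1, 0.5)) {
    n_tol <- sum(match_features(gen$table, lib, mass_tol_ppm = tol)$accepted)
    if (tol == 6) n_prev <- n_tol
    expect_lte(n_tol, n_prev)
    n_prev <- n_tol
  }
})

test_that("accepted annotations always satisfy the gates", {
  cfg <- generator_config(seed = 13, n_library = 80, n_true_metabolites = 60,
                          n_exochemicals = 30)
  lib <- generate_library(cfg)
  gen <- generate_feature_tables(cfg, lib)
  std <- generate_rt_standards(cfg, lib)
  ann <- match_features(gen$table, lib, rt_model = fit_rt_model(std))
  expect_true(all(abs(ann$mass_error_ppm) <= 6))
  gated <- !is.na(ann$rt_deviation_fraction)
  expect_true(all(ann$rt_deviation_fraction[gated] <= 0.45))
})
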