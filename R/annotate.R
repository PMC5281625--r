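# Putative metabolite identification: exact-mass library matching,
# six-descriptor retention-time regression, RT gating, confidence scoring,
# best-match selection and pathway roll-up.

#' Default database priority order
#'
#' Ranked vector mapping source database to priority rank (1 = highest).
#' When a feature matches compounds from several databases at equal
#' confidence, the lower rank wins.
#' @export
default_db_priority <- c(KEGG = 1L, MetaCyc = 2L, HMDB = 3L, LipidMaps = 4L)

#' Read a compound library from delimited text
#'
#' Expected tab-separated columns: `compound_id`, `name`, `formula`,
#' `source_db`, `db_priority`, `pathway_ids` (semicolon-joined, may be
#' empty), `d1`..`d6` (the six physico-chemical descriptors; may be blank),
#' `reference_rt` (minutes, blank when no authentic standard exists).
#'
#' @param path File path.
#' @return Tibble with one row per library compound, descriptor columns
#'   `d1`..`d6`, a `pathways` list-column, and a `theoretical_mass` column
#'   computed from the formula.
#' @export
read_compound_library <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "name", "formula", "source_db", "db_priority",
            "pathway_ids", paste0("d", 1:6), "reference_rt")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("library file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lib <- tibble::as_tibble(raw)
  lib$compound_id <- as.character(lib$compound_id)
  lib$pathways <- lapply(strsplit(as.character(lib$pathway_ids), ";"),
                         function(x) x[nzchar(x)])
  lib$theoretical_mass <- vapply(lib$formula, monoisotopic_mass, numeric(1),
                                 USE.NAMES = FALSE)
  lib
}

#' Fit the retention-time prediction model
#'
#' Ordinary least squares of observed retention time on six physico-chemical
#' descriptors plus an intercept (a quantitative structure-retention
#' relationship, QSRR). Calibration uses authentic standards with known
#' retention times; at least 8 standards are required (7 parameters + 1
#' residual degree of freedom) and the descriptor matrix must be full rank.
#'
#' @param standards Data frame or tibble with descriptor columns `d1`..`d6`
#'   and an `rt` column of observed retention times (minutes).
#' @return An `rt_model` list: `intercept`, `coefficients` (length 6),
#'   `n_calibration`, `residual_sd`, and the underlying `fit`.
#' @export
fit_rt_model <- function(standards) {
  standards <- as.data.frame(standards)
  need <- c(paste0("d", 1:6), "rt")
  missing <- setdiff(need, names(standards))
  if (length(missing)) {
    stop("standards need column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(standards)
  if (n < 8L) {
    stop("retention-time calibration needs >= 8 standards (got ", n, ")",
         call. = FALSE)
  }
  X <- cbind(1, as.matrix(standards[, paste0("d", 1:6)]))
  if (qr(X)$rank < ncol(X)) {
    stop("descriptor matrix is rank deficient; cannot calibrate", call. = FALSE)
  }
  fit <- lm(rt ~ d1 + d2 + d3 + d4 + d5 + d6, data = standards)
  structure(
    list(
      intercept = unname(coef(fit)[1]),
      coefficients = unname(coef(fit)[-1]),
      n_calibration = n,
      residual_sd = sqrt(sum(fit$residuals^2) / fit$df.residual),
      fit = fit
    ),
    class = "rt_model"
  )
}

#' @export
print.rt_model <- function(x, ...) {
  cat("<rt_model> calibrated on ", x$n_calibration, " standards; residual sd ",
      sprintf("%.3f", x$residual_sd), " min\n", sep = "")
  invisible(x)
}

#' Predict retention time for compounds with descriptors
#'
#' @param model An `rt_model`.
#' @param descriptors Numeric vector of 6 descriptors, or a matrix/data
#'   frame with columns `d1`..`d6`. Rows with any missing descriptor get
#'   `NA` (no prediction; the annotation then proceeds without an RT gate).
#' @return Predicted retention times in minutes.
#' @export
predict_rt <- function(model, descriptors) {
  stopifnot(inherits(model, "rt_model"))
  if (is.null(dim(descriptors))) {
    descriptors <- matrix(descriptors, nrow = 1,
                          dimnames = list(NULL, paste0("d", 1:6)))
  }
  D <- as.matrix(as.data.frame(descriptors)[, paste0("d", 1:6)])
  drop(model$intercept + D %*% model$coefficients)
}

#' Match features against a compound library by exact mass
#'
#' A library compound is a candidate for a feature when the signed mass
#' error of the feature's neutral mass against the compound's monoisotopic
#' mass is within `mass_tol_ppm`. For positive-ion-mode features (where the
#' HILIC retention-time model applies) a candidate whose observed retention
#' time deviates from the model prediction by more than `rt_reject_fraction`
#' (relative to the prediction) is rejected; negative-mode features skip the
#' RT gate, as do compounds without descriptors. Each retained candidate
#' receives a 1-10 confidence score ([confidence_score()]); the accepted
#' annotation per feature is the best-scoring candidate ([select_best()]).
#'
#' @param table A `feature_table`.
#' @param library Compound library tibble ([read_compound_library()] or
#'   [generate_library()]).
#' @param mass_tol_ppm Mass tolerance, ppm (inclusive).
#' @param rt_model Optional `rt_model`; without it no RT gating is done.
#' @param rt_reject_fraction Maximum |observed - predicted| / predicted.
#' @param db_priority Named rank vector, see [default_db_priority].
#' @return Tibble of candidate annotations (one row per feature x candidate)
#'   with columns `feature_id`, `compound_id`, `mass_error_ppm`,
#'   `predicted_rt`, `rt_deviation_fraction`, `confidence`, `accepted`;
#'   `accepted` marks the selected best candidate per feature.
#' @export
match_features <- function(table, library, mass_tol_ppm = 6, rt_model = NULL,
                           rt_reject_fraction = 0.45,
                           db_priority = default_db_priority) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(library) == 0L) stop("compound library is empty", call. = FALSE)
  lib <- library
  if (!"theoretical_mass" %in% names(lib)) {
    lib$theoretical_mass <- vapply(lib$formula, monoisotopic_mass, numeric(1),
                                   USE.NAMES = FALSE)
  }
  lib$priority_rank <- lib$db_priority
  if (!is.null(db_priority) && "source_db" %in% names(lib)) {
    mapped <- unname(db_priority[as.character(lib$source_db)])
    lib$priority_rank <- ifelse(is.na(mapped), lib$db_priority, mapped)
  }
  has_desc <- if (all(paste0("d", 1:6) %in% names(lib))) {
    stats::complete.cases(as.data.frame(lib)[, paste0("d", 1:6)])
  } else rep(FALSE, nrow(lib))
  pred <- rep(NA_real_, nrow(lib))
  if (!is.null(rt_model) && any(has_desc)) {
    pred[has_desc] <- predict_rt(rt_model, lib[has_desc, , drop = FALSE])
  }

  feats <- table$features
  rows <- vector("list", nrow(feats))
  for (i in seq_len(nrow(feats))) {
    err <- mass_error(feats$neutral_mass[i], lib$theoretical_mass)$ppm
    hit <- which(abs(err) <= mass_tol_ppm)
    if (!length(hit)) next
    dev <- rep(NA_real_, length(hit))
    gated <- feats$ion_mode[i] %in% c("positive", "both") & !is.na(pred[hit])
    dev[gated] <- abs(feats$rt[i] - pred[hit][gated]) / pred[hit][gated]
    ok <- is.na(dev) | dev <= rt_reject_fraction
    hit <- hit[ok]; dev <- dev[ok]
    if (!length(hit)) next
    rows[[i]] <- tibble::tibble(
      feature_id = feats$feature_id[i],
      compound_id = lib$compound_id[hit],
      mass_error_ppm = err[hit],
      predicted_rt = pred[hit],
      rt_deviation_fraction = dev,
      priority_rank = lib$priority_rank[hit],
      reference_rt = if ("reference_rt" %in% names(lib)) {
        lib$reference_rt[hit]
      } else NA_real_,
      observed_rt = feats$rt[i]
    )
  }
  cand <- dplyr::bind_rows(rows)
  if (nrow(cand) == 0L) {
    return(tibble::tibble(
      feature_id = character(), compound_id = character(),
      mass_error_ppm = numeric(), predicted_rt = numeric(),
      rt_deviation_fraction = numeric(), priority_rank = integer(),
      confidence = integer(), accepted = logical()
    ))
  }
  cand$confidence <- confidence_score(
    mass_error_ppm = cand$mass_error_ppm,
    rt_deviation_fraction = cand$rt_deviation_fraction,
    priority_rank = cand$priority_rank,
    max_tol_ppm = mass_tol_ppm,
    standard_match = !is.na(cand$reference_rt) &
      abs(cand$observed_rt - cand$reference_rt) <=
        0.10 * pmax(cand$reference_rt, .Machine$double.eps)
  )
  cand <- dplyr::group_by(cand, .data$feature_id) |>
    dplyr::mutate(accepted = seq_len(dplyr::n()) == best_candidate_index(
      .data$confidence, .data$priority_rank, .data$mass_error_ppm,
      .data$compound_id)) |>
    dplyr::ungroup()
  cand
}

#' Confidence score for a putative identification
#'
#' A deterministic 1-10 rubric built from the three ingredients that matter
#' for putative LC-MS identifications: mass-error magnitude, retention-time
#' deviation, and database priority. Starting from 10, penalties are
#' `3 * |ppm| / max_tol_ppm` for mass error, `3 * deviation / 0.45` for the
#' retention-time deviation (a flat 1 when no prediction is available), and
#' `min(rank - 1, 3)` for database priority. The fractional score is
#' floored to an integer and clamped to \[1, 10\]. A match against an
#' authentic standard's reference retention time (within 10%) forces 10.
#'
#' @param mass_error_ppm Signed ppm error (vectorized).
#' @param rt_deviation_fraction Relative RT deviation; `NA` = no prediction.
#' @param priority_rank Database priority rank (1 = highest).
#' @param max_tol_ppm Mass tolerance the penalty is scaled by.
#' @param standard_match Logical: observed RT matches an authentic
#'   standard's reference RT within 10%.
#' @return Integer confidence scores in 1..10.
#' @export
confidence_score <- function(mass_error_ppm, rt_deviation_fraction = NA,
                             priority_rank = 1L, max_tol_ppm = 6,
                             standard_match = FALSE) {
  n <- max(length(mass_error_ppm), length(rt_deviation_fraction),
           length(priority_rank), length(standard_match))
  mass_pen <- 3 * abs(rep_len(mass_error_ppm, n)) / max_tol_ppm
  dev <- rep_len(rt_deviation_fraction, n)
  rt_pen <- ifelse(is.na(dev), 1, 3 * dev / 0.45)
  pri_pen <- pmin(rep_len(priority_rank, n) - 1, 3)
  score <- pmax(pmin(floor(10 - mass_pen - rt_pen - pri_pen + 1e-9), 10), 1)
  score[rep_len(standard_match, n)] <- 10L
  as.integer(score)
}

# index of the winning candidate under the deterministic total order:
# highest confidence, then lowest priority rank, then smallest |ppm|,
# then lexicographic compound_id
best_candidate_index <- function(confidence, priority_rank, mass_error_ppm,
                                 compound_id) {
  order(-confidence, priority_rank, abs(mass_error_ppm), compound_id)[1]
}

#' Select the best annotation among candidates for one feature
#'
#' The candidate with the highest confidence wins; ties are broken by lower
#' database priority rank, then smaller absolute mass error, then
#' lexicographic compound id, so the winner never depends on input order.
#'
#' @param candidates Tibble of candidate annotations for a single feature
#'   (columns as produced by [match_features()]).
#' @return The winning row, or `NULL` when `candidates` is empty.
#' @export
select_best <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(NULL)
  idx <- best_candidate_index(candidates$confidence,
                              candidates$priority_rank,
                              candidates$mass_error_ppm,
                              candidates$compound_id)
  candidates[idx, , drop = FALSE]
}

#' Roll accepted annotations up to pathways
#'
#' Each accepted annotation contributes its compound's pathway memberships;
#' a compound belonging to several pathways counts once in each. Compounds
#' with no pathway membership accumulate under `"unassigned"`.
#'
#' @param annotations Annotation tibble from [match_features()]; only rows
#'   with `accepted = TRUE` are used.
#' @param library Compound library with a `pathways` list-column.
#' @param abundance Optional named vector of per-feature abundances to sum
#'   per pathway (e.g. one sample's means).
#' @return Tibble `pathway`, `n_metabolites`, `total_abundance`.
#' @export
map_pathways <- function(annotations, library, abundance = NULL) {
  acc <- annotations[annotations$accepted, , drop = FALSE]
  pw <- library$pathways[match(acc$compound_id, library$compound_id)]
  pw <- lapply(pw, function(p) if (length(p)) p else "unassigned")
  ab <- if (is.null(abundance)) rep(0, nrow(acc)) else {
    unname(abundance[acc$feature_id])
  }
  long <- tibble::tibble(
    pathway = unlist(pw),
    feature_id = rep(acc$feature_id, lengths(pw)),
    abundance = rep(ab, lengths(pw))
  )
  dplyr::summarise(
    dplyr::group_by(long, .data$pathway),
    n_metabolites = dplyr::n(),
    total_abundance = sum(.data$abundance),
    .groups = "drop"
  )
}
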