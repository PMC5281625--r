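# Homolog-series screening for fumarate-addition metabolites
# (alkylsuccinates, benzylsuccinates) and single-compound aerobic targets.

#' Define a homolog series for targeted screening
#'
#' Two built-in formula rules cover the fumarate-addition metabolite
#' families: `"alkylsuccinate"` (succinate + n-carbon alkyl chain,
#' C(n+4)H(2n+6)O4, so n = 2 is ethylsuccinic acid) and
#' `"benzylsuccinate"` (benzylsuccinate + m extra alkyl carbons,
#' C(11+m)H(12+2m)O4, so m = 0 is benzylsuccinic acid and m = 1 the
#' methylbenzylsuccinate / phenylethylsuccinate isomers).
#'
#' Anchor retention times come from authentic standards (or culture
#' extracts known to produce the series); with two or more anchors the
#' expected RT of other members is interpolated linearly in carbon number.
#'
#' @param series_name `"alkylsuccinate"` or `"benzylsuccinate"`.
#' @param n_range Integer vector of carbon numbers to generate.
#' @param anchor_rts Optional data frame with columns `n`, `rt` (minutes).
#' @return A `homolog_series` list.
#' @export
homolog_series <- function(series_name = c("alkylsuccinate", "benzylsuccinate"),
                           n_range, anchor_rts = NULL) {
  series_name <- match.arg(series_name)
  n_range <- as.integer(n_range)
  min_n <- if (series_name == "alkylsuccinate") 1L else 0L
  if (any(n_range < min_n)) {
    stop("carbon number out of range for ", series_name,
         " (minimum ", min_n, ")", call. = FALSE)
  }
  if (!is.null(anchor_rts)) {
    anchor_rts <- as.data.frame(anchor_rts)
    stopifnot(all(c("n", "rt") %in% names(anchor_rts)))
  }
  structure(
    list(series_name = series_name, n_range = n_range,
         anchor_rts = anchor_rts),
    class = "homolog_series"
  )
}

series_formula <- function(series_name, n) {
  switch(series_name,
    alkylsuccinate = sprintf("C%dH%dO4", n + 4L, 2L * n + 6L),
    benzylsuccinate = sprintf("C%dH%dO4", 11L + n, 12L + 2L * n),
    stop("unknown series '", series_name, "'", call. = FALSE)
  )
}

#' Generate the members of a homolog series
#'
#' @param series A `homolog_series` (or a series name, with `n_range`).
#' @param n_range Carbon numbers, when `series` is given as a name.
#' @return Tibble `series_name`, `n`, `formula`, `theoretical_mass` (Da).
#' @export
#' @examples
#' generate_series("alkylsuccinate", 2:6)
generate_series <- function(series, n_range = NULL) {
  if (is.character(series)) {
    series <- homolog_series(series, n_range)
  }
  stopifnot(inherits(series, "homolog_series"))
  formulas <- vapply(series$n_range, function(n) {
    series_formula(series$series_name, n)
  }, character(1))
  tibble::tibble(
    series_name = series$series_name,
    n = series$n_range,
    formula = formulas,
    theoretical_mass = vapply(formulas, monoisotopic_mass, numeric(1),
                              USE.NAMES = FALSE)
  )
}

#' Expected retention time of a series member
#'
#' Piecewise-linear interpolation of anchor retention times against carbon
#' number; members beyond the anchor range are linearly extrapolated from
#' the nearest two anchors and flagged. With a single anchor only that
#' carbon number can be RT-gated; with none, screening is mass-only.
#'
#' @param series A `homolog_series` with anchors.
#' @param n Carbon number(s).
#' @return Tibble `n`, `expected_rt` (NA when no prediction is possible),
#'   `extrapolated`.
#' @export
expected_rt <- function(series, n) {
  stopifnot(inherits(series, "homolog_series"))
  a <- series$anchor_rts
  if (is.null(a) || nrow(a) == 0L) {
    return(tibble::tibble(n = n, expected_rt = NA_real_, extrapolated = FALSE))
  }
  a <- a[order(a$n), , drop = FALSE]
  if (nrow(a) == 1L) {
    return(tibble::tibble(
      n = n,
      expected_rt = ifelse(n == a$n, a$rt, NA_real_),
      extrapolated = FALSE
    ))
  }
  interp <- stats::approx(a$n, a$rt, xout = n, rule = 1)$y
  below <- n < min(a$n); above <- n > max(a$n)
  lo <- a[1:2, ]; hi <- a[(nrow(a) - 1):nrow(a), ]
  slope_lo <- (lo$rt[2] - lo$rt[1]) / (lo$n[2] - lo$n[1])
  slope_hi <- (hi$rt[2] - hi$rt[1]) / (hi$n[2] - hi$n[1])
  interp[below] <- lo$rt[1] + slope_lo * (n[below] - lo$n[1])
  interp[above] <- hi$rt[2] + slope_hi * (n[above] - hi$n[2])
  tibble::tibble(n = n, expected_rt = interp, extrapolated = below | above)
}

#' Screen a feature table for homolog-series metabolites
#'
#' A feature is a detection for a series member when its neutral mass is
#' within `mass_tol_ppm` of the member's theoretical monoisotopic mass AND,
#' when an expected retention time is available, its retention time is
#' within `rt_tol_fraction` of that expectation (relative to the expected
#' value). All qualifying features are reported - co-eluting isomers
#' legitimately co-qualify - with `top_hit` marking the most abundant
#' feature per (series, n). Detections without an RT expectation carry
#' `mass_only = TRUE`.
#'
#' @param table A `feature_table` (typically abundance-filtered).
#' @param series A `homolog_series` or list of them.
#' @param mass_tol_ppm Mass tolerance, ppm (inclusive; default +-2).
#' @param rt_tol_fraction RT tolerance relative to the expected RT
#'   (inclusive; default +-10%).
#' @return Tibble of detections: `series_name`, `n`, `formula`,
#'   `feature_id`, `mass_error_ppm`, `rt_deviation_fraction`, `mass_only`,
#'   `total_abundance`, `top_hit`.
#' @export
screen_series <- function(table, series, mass_tol_ppm = 2,
                          rt_tol_fraction = 0.10) {
  stopifnot(inherits(table, "feature_table"))
  if (inherits(series, "homolog_series")) series <- list(series)
  means <- sample_means(table)
  totals <- tapply(means$mean_abundance, means$feature_id, sum)
  feats <- table$features
  out <- list()
  for (s in series) {
    members <- generate_series(s)
    ert <- expected_rt(s, members$n)
    for (k in seq_len(nrow(members))) {
      err <- mass_error(feats$neutral_mass, members$theoretical_mass[k])$ppm
      hit <- which(abs(err) <= mass_tol_ppm)
      if (!length(hit)) next
      exp_rt <- ert$expected_rt[k]
      dev <- if (is.na(exp_rt)) rep(NA_real_, length(hit)) else {
        abs(feats$rt[hit] - exp_rt) / exp_rt
      }
      ok <- is.na(dev) | dev <= rt_tol_fraction
      hit <- hit[ok]; dev <- dev[ok]
      if (!length(hit)) next
      det <- tibble::tibble(
        series_name = s$series_name,
        n = members$n[k],
        formula = members$formula[k],
        feature_id = feats$feature_id[hit],
        mass_error_ppm = err[hit],
        rt_deviation_fraction = dev,
        mass_only = is.na(dev),
        total_abundance = unname(totals[feats$feature_id[hit]])
      )
      det$top_hit <- seq_len(nrow(det)) == which.max(det$total_abundance)
      out[[length(out) + 1]] <- det
    }
  }
  if (!length(out)) {
    return(tibble::tibble(
      series_name = character(), n = integer(), formula = character(),
      feature_id = character(), mass_error_ppm = numeric(),
      rt_deviation_fraction = numeric(), mass_only = logical(),
      total_abundance = numeric(), top_hit = logical()
    ))
  }
  dplyr::bind_rows(out)
}

#' Screen single-compound targets (e.g. aerobic degradation products)
#'
#' Hydroxylated aromatic products of aerobic hydrocarbon degradation are
#' screened as individual targets with per-compound reference retention
#' times rather than as homolog series.
#'
#' @param table A `feature_table`.
#' @param targets Data frame with columns `compound`, `formula`, and
#'   optionally `reference_rt` (minutes; NA = mass-only).
#' @inheritParams screen_series
#' @return Tibble of detections, one row per qualifying feature x target.
#' @export
screen_targets <- function(table, targets, mass_tol_ppm = 2,
                           rt_tol_fraction = 0.10) {
  stopifnot(inherits(table, "feature_table"))
  targets <- as.data.frame(targets)
  if (!"reference_rt" %in% names(targets)) targets$reference_rt <- NA_real_
  feats <- table$features
  rows <- list()
  for (k in seq_len(nrow(targets))) {
    theo <- monoisotopic_mass(targets$formula[k])
    err <- mass_error(feats$neutral_mass, theo)$ppm
    hit <- which(abs(err) <= mass_tol_ppm)
    if (!length(hit)) next
    ref <- targets$reference_rt[k]
    dev <- if (is.na(ref)) rep(NA_real_, length(hit)) else {
      abs(feats$rt[hit] - ref) / ref
    }
    ok <- is.na(dev) | dev <= rt_tol_fraction
    hit <- hit[ok]; dev <- dev[ok]
    if (!length(hit)) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      compound = targets$compound[k],
      formula = targets$formula[k],
      feature_id = feats$feature_id[hit],
      mass_error_ppm = err[hit],
      rt_deviation_fraction = dev,
      mass_only = is.na(dev)
    )
  }
  if (!length(rows)) {
    return(tibble::tibble(
      compound = character(), formula = character(), feature_id = character(),
      mass_error_ppm = numeric(), rt_deviation_fraction = numeric(),
      mass_only = logical()
    ))
  }
  dplyr::bind_rows(rows)
}
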