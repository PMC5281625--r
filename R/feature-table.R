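# The aligned LC-MS feature table: the central container of the
# metabolomics half of the pipeline.

#' Construct an aligned feature table
#'
#' A `feature_table` holds one row per aligned LC-MS feature (neutral mass,
#' retention time, ion mode) together with a long table of abundances in
#' instrument units (i.u.), one value per (feature, sample, replicate).
#' Every feature must have an abundance for every (sample, replicate) cell;
#' missing cells are filled with 0.
#'
#' @param features Tibble with columns `feature_id`, `neutral_mass` (Da),
#'   `rt` (min), `ion_mode` (`"positive"`, `"negative"` or `"both"`).
#' @param abundances Tibble with columns `feature_id`, `sample`,
#'   `replicate`, `abundance` (i.u., >= 0).
#' @param sample_names Ordered sample set; defaults to the samples present.
#' @param replicate_count Replicates per sample; defaults to the maximum
#'   replicate index present.
#' @param provenance Free-text note on where the table came from.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, abundances,
                          sample_names = NULL, replicate_count = NULL,
                          provenance = "") {
  features <- tibble::as_tibble(features)
  abundances <- tibble::as_tibble(abundances)
  stopifnot(
    all(c("feature_id", "neutral_mass", "rt", "ion_mode") %in% names(features)),
    all(c("feature_id", "sample", "replicate", "abundance") %in% names(abundances))
  )
  if (anyDuplicated(features$feature_id)) {
    stop("feature_ids must be unique", call. = FALSE)
  }
  if (nrow(features) &&
      (any(features$neutral_mass <= 0) || any(features$rt < 0))) {
    stop("features require neutral_mass > 0 and rt >= 0", call. = FALSE)
  }
  if (nrow(abundances) && any(abundances$abundance < 0)) {
    stop("abundances must be >= 0", call. = FALSE)
  }
  if (is.null(sample_names)) sample_names <- unique(abundances$sample)
  if (is.null(replicate_count)) {
    replicate_count <- if (nrow(abundances)) max(abundances$replicate) else 0L
  }
  # complete the (feature, sample, replicate) grid with zeros
  if (nrow(features)) {
    grid <- tidyr::expand_grid(
      feature_id = features$feature_id,
      sample = sample_names,
      replicate = seq_len(replicate_count)
    )
    abundances <- dplyr::left_join(
      grid, abundances, by = c("feature_id", "sample", "replicate")
    )
    abundances$abundance[is.na(abundances$abundance)] <- 0
  }
  structure(
    list(
      features = features,
      abundances = abundances,
      sample_names = sample_names,
      replicate_count = as.integer(replicate_count),
      provenance = provenance
    ),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$features), " features, ",
      length(x$sample_names), " samples x ", x$replicate_count,
      " replicates\n", sep = "")
  if (nrow(x$features)) {
    modes <- table(x$features$ion_mode)
    cat("  ion modes: ", paste(names(modes), modes, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of features in a table
#' @param table A `feature_table`.
#' @return Integer feature count.
#' @export
n_features <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  nrow(table$features)
}

#' Per-sample mean abundances
#'
#' The per-sample abundance of a feature is the mean of its replicate
#' measurements; this is the quantity used by all downstream filters and
#' statistics.
#'
#' @param table A `feature_table`.
#' @return Tibble `feature_id`, `sample`, `mean_abundance`.
#' @export
sample_means <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  dplyr::summarise(
    dplyr::group_by(table$abundances, .data$feature_id, .data$sample),
    mean_abundance = mean(.data$abundance), .groups = "drop"
  )
}

#' Replicate abundance matrix (features x observation columns)
#'
#' @param table A `feature_table`.
#' @return Numeric matrix, rows = features, columns = `sample.replicate`.
#' @export
abundance_matrix <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  ab <- table$abundances
  ab$obs <- paste(ab$sample, ab$replicate, sep = ".")
  wide <- tidyr::pivot_wider(
    ab[, c("feature_id", "obs", "abundance")],
    names_from = "obs", values_from = "abundance"
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$feature_id
  obs_order <- as.vector(outer(seq_len(table$replicate_count),
                               table$sample_names,
                               function(r, s) paste(s, r, sep = ".")))
  m[match(table$features$feature_id, rownames(m)),
    intersect(obs_order, colnames(m)), drop = FALSE]
}

#' Read / write a feature table as delimited text
#'
#' The canonical layout is long: one row per (feature, sample, replicate)
#' with columns `feature_id`, `neutral_mass_da`, `rt_min`, `ion_mode`,
#' `sample`, `replicate`, `abundance_iu` (tab-separated, header mandatory).
#' The same layout, read with [read_raw_features()], is the input of
#' [align_features()], where each row is an unaligned single-replicate peak.
#'
#' @param path File path.
#' @param sample_names,replicate_count Optional overrides passed to
#'   [feature_table()].
#' @return `read_feature_table()` returns a `feature_table`;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
read_feature_table <- function(path, sample_names = NULL,
                               replicate_count = NULL) {
  raw <- read_raw_features(path)
  feats <- dplyr::distinct(
    raw[, c("feature_id", "neutral_mass", "rt", "ion_mode")]
  )
  feature_table(
    feats, raw[, c("feature_id", "sample", "replicate", "abundance")],
    sample_names = sample_names, replicate_count = replicate_count,
    provenance = path
  )
}

#' @rdname read_feature_table
#' @param table A `feature_table` to write.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  long <- dplyr::left_join(table$abundances, table$features, by = "feature_id")
  out <- data.frame(
    feature_id = long$feature_id,
    neutral_mass_da = long$neutral_mass,
    rt_min = long$rt,
    ion_mode = long$ion_mode,
    sample = long$sample,
    replicate = long$replicate,
    abundance_iu = long$abundance
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_feature_table
#' @param noise_factor Peaks below `noise_factor` times the optional
#'   `noise_iu` column are dropped on read (applied only when the column is
#'   present; mirrors threshold-times-noise peak picking upstream).
#' @export
read_raw_features <- function(path, noise_factor = 3) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("feature_id", "neutral_mass_da", "rt_min", "ion_mode",
            "sample", "replicate", "abundance_iu")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("feature file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if ("noise_iu" %in% names(raw)) {
    raw <- raw[raw$abundance_iu >= noise_factor * raw$noise_iu, , drop = FALSE]
  }
  tibble::tibble(
    feature_id = as.character(raw$feature_id),
    neutral_mass = raw$neutral_mass_da,
    rt = raw$rt_min,
    ion_mode = raw$ion_mode,
    sample = as.character(raw$sample),
    replicate = as.integer(raw$replicate),
    abundance = raw$abundance_iu
  )
}
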