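# System-level metabolome statistics: the odd-mass RN statistic,
# high- vs low-corrosion system sums, differential features, abundance-ratio
# distribution, identified:non-identified ratios, and PCA.

#' Default sample-to-system map for the two-pipeline comparison
#'
#' Samples from pig runs 3 and 11 of the low-corrosion (LC) and
#' high-corrosion (HC) pipelines.
#' @export
default_system_map <- c(LC3 = "LC", LC11 = "LC", HC3 = "HC", HC11 = "HC")

#' The RN odd-nominal-mass abundance statistic
#'
#' Fraction (as a percent) of a sample's total feature abundance carried by
#' features whose neutral mass rounds to an odd nominal mass. By the
#' nitrogen rule, odd-nominal-mass CHNOPS molecules contain an odd number
#' of nitrogen atoms, so RN tracks the weight of organonitrogen compounds
#' in the metabolome without requiring identifications:
#' \deqn{R_N = 100 \times \frac{\sum \mathrm{abundance(odd\mbox{-}mass\ features)}}
#'   {\sum \mathrm{abundance(all\ features)}}}
#'
#' Abundances are per-sample replicate means. For annotated features with a
#' known formula, the formula's nitrogen parity overrides mass rounding
#' (the rule is exact once the composition is known).
#'
#' @param table A `feature_table`.
#' @param sample Sample name.
#' @param feature_ids Optional subset of feature ids (e.g. identified
#'   features only); default all.
#' @param annotations,library Optional accepted annotations and library;
#'   when given, annotated features take their parity from the matched
#'   formula's nitrogen count.
#' @return A one-row tibble: `sample`, `subset`, `rn_percent`,
#'   `odd_abundance`, `total_abundance`.
#' @export
rn_statistic <- function(table, sample, feature_ids = NULL,
                         annotations = NULL, library = NULL) {
  stopifnot(inherits(table, "feature_table"))
  means <- sample_means(table)
  means <- means[means$sample == sample, , drop = FALSE]
  subset_label <- "all"
  if (!is.null(feature_ids)) {
    means <- means[means$feature_id %in% feature_ids, , drop = FALSE]
    subset_label <- "subset"
  }
  feats <- table$features[match(means$feature_id, table$features$feature_id), ]
  odd <- nitrogen_parity(feats$neutral_mass)$is_odd
  if (!is.null(annotations) && !is.null(library)) {
    acc <- annotations[annotations$accepted, , drop = FALSE]
    idx <- match(means$feature_id, acc$feature_id)
    hit <- !is.na(idx)
    if (any(hit)) {
      formulas <- library$formula[match(acc$compound_id[idx[hit]],
                                        library$compound_id)]
      n_count <- vapply(formulas, function(f) {
        counts <- parse_formula(f)
        if ("N" %in% names(counts)) as.integer(counts[["N"]]) else 0L
      }, integer(1))
      odd[hit] <- n_count %% 2L == 1L
    }
  }
  total <- sum(means$mean_abundance)
  if (total <= 0) {
    stop("total abundance in sample '", sample,
         "' is zero; RN is undefined", call. = FALSE)
  }
  odd_ab <- sum(means$mean_abundance[odd])
  tibble::tibble(
    sample = sample, subset = subset_label,
    rn_percent = 100 * odd_ab / total,
    odd_abundance = odd_ab, total_abundance = total
  )
}

#' Per-feature abundance summed over each system's samples
#'
#' The system abundance of a feature is the sum of its per-sample mean
#' abundances over the samples assigned to that system (e.g. pig runs 3 and
#' 11 of each pipeline).
#'
#' @param table A `feature_table`.
#' @param system_map Named character vector, sample -> system.
#' @return Tibble `feature_id` plus one column per system.
#' @export
system_sums <- function(table, system_map = default_system_map) {
  stopifnot(inherits(table, "feature_table"))
  means <- sample_means(table)
  unmapped <- setdiff(unique(means$sample), names(system_map))
  if (length(unmapped)) {
    stop("sample(s) not in system map: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  means$system <- unname(system_map[means$sample])
  sums <- dplyr::summarise(
    dplyr::group_by(means, .data$feature_id, .data$system),
    abundance = sum(.data$mean_abundance), .groups = "drop"
  )
  tidyr::pivot_wider(sums, names_from = "system", values_from = "abundance",
                     values_fill = 0)
}

#' Differential features between two systems
#'
#' A feature is enriched in system A when at least one system's summed
#' abundance strictly exceeds `min_abundance` AND the A:B abundance ratio
#' is at least `min_ratio` (a zero denominator with a numerator above the
#' gate counts as infinitely enriched). The two enriched sets are disjoint
#' by construction.
#'
#' @param sys System-abundance tibble from [system_sums()].
#' @param systems Length-2 character vector naming the columns to compare
#'   (first vs second).
#' @param min_abundance Abundance gate, i.u. (strict >, in at least one
#'   system).
#' @param min_ratio Minimum abundance ratio (inclusive).
#' @return List: `per_feature` tibble (`feature_id`, both abundances,
#'   `ratio`, `enriched_in`), and the two enrichment counts.
#' @export
differential_features <- function(sys, systems = c("HC", "LC"),
                                  min_abundance = 10000, min_ratio = 5) {
  stopifnot(all(systems %in% names(sys)), length(systems) == 2)
  a <- sys[[systems[1]]]
  b <- sys[[systems[2]]]
  gate <- a > min_abundance | b > min_abundance
  ratio_ab <- ifelse(b > 0, a / b, ifelse(a > 0, Inf, NA_real_))
  ratio_ba <- ifelse(a > 0, b / a, ifelse(b > 0, Inf, NA_real_))
  enr_a <- gate & !is.na(ratio_ab) & ratio_ab >= min_ratio
  enr_b <- gate & !is.na(ratio_ba) & ratio_ba >= min_ratio
  per <- tibble::tibble(
    feature_id = sys$feature_id,
    !!systems[1] := a, !!systems[2] := b,
    ratio = ratio_ab,
    enriched_in = dplyr::case_when(
      enr_a ~ systems[1], enr_b ~ systems[2], TRUE ~ NA_character_
    )
  )
  out <- list(per_feature = per)
  out[[paste0(tolower(systems[1]), "_enriched_count")]] <- sum(enr_a)
  out[[paste0(tolower(systems[2]), "_enriched_count")]] <- sum(enr_b)
  out
}

#' Fraction of features with similar abundance in both systems
#'
#' Among features detected in both systems (both abundances > 0), the
#' fraction whose larger:smaller abundance ratio is strictly below `fold`.
#' Features with a zero on one side are tallied separately as one-sided.
#'
#' @inheritParams differential_features
#' @param fold Similarity fold threshold (strict <).
#' @return List: `fraction_similar`, `n_two_sided`, `n_one_sided`,
#'   `n_zero_both`.
#' @export
ratio_distribution <- function(sys, systems = c("HC", "LC"), fold = 3) {
  stopifnot(all(systems %in% names(sys)))
  a <- sys[[systems[1]]]
  b <- sys[[systems[2]]]
  two <- a > 0 & b > 0
  one <- (a > 0) != (b > 0)
  r <- pmax(a[two], b[two]) / pmin(a[two], b[two])
  list(
    fraction_similar = if (any(two)) mean(r < fold) else NA_real_,
    n_two_sided = sum(two),
    n_one_sided = sum(one),
    n_zero_both = sum(!two & !one)
  )
}

#' Identified:non-identified ratio among a sample's most abundant features
#'
#' Ranks features by per-sample mean abundance (ties broken by feature id),
#' takes the top `n`, and reports the ratio of features with an accepted
#' annotation to those without.
#'
#' @param table A `feature_table`.
#' @param annotations Annotation tibble from [match_features()].
#' @param sample Sample name.
#' @param n Number of top features to consider.
#' @return List: `ratio` (Inf when all identified, flagged),
#'   `n_identified`, `n_non_identified`.
#' @export
id_ratio_top_n <- function(table, annotations, sample, n = 200) {
  stopifnot(inherits(table, "feature_table"))
  means <- sample_means(table)
  means <- means[means$sample == sample, , drop = FALSE]
  if (n > nrow(means)) {
    stop("n = ", n, " exceeds the feature count (", nrow(means), ")",
         call. = FALSE)
  }
  ord <- order(-means$mean_abundance, means$feature_id)
  top <- means$feature_id[ord][seq_len(n)]
  identified_ids <- unique(annotations$feature_id[annotations$accepted])
  n_id <- sum(top %in% identified_ids)
  list(
    ratio = if (n_id == n) Inf else n_id / (n - n_id),
    all_identified = n_id == n,
    n_identified = n_id,
    n_non_identified = n - n_id
  )
}

#' Principal component analysis of replicate abundance profiles
#'
#' Features with abundance of at least `min_abundance` in one or more
#' samples are retained; observations are the sample x replicate abundance
#' vectors. Abundances are optionally log10(x+1)-transformed, then
#' mean-centered per feature (no unit-variance scaling: the abundance scale
#' is meaningful). Components come from singular value decomposition via
#' [stats::prcomp()].
#'
#' @param table A `feature_table` with >= 3 observation columns.
#' @param min_abundance Per-sample mean abundance gate (>= in at least one
#'   sample).
#' @param scale `"linear"` or `"log"`.
#' @return List of class `metabolome_pca`: `scores` (observations x PCs,
#'   with `sample` and `replicate` columns), `loadings`,
#'   `explained_variance` (fractions), `n_features`.
#' @export
pca_features <- function(table, min_abundance = 10000,
                         scale = c("linear", "log")) {
  scale <- match.arg(scale)
  stopifnot(inherits(table, "feature_table"))
  n_obs <- length(table$sample_names) * table$replicate_count
  if (n_obs < 3L) stop("PCA needs at least 3 observation columns", call. = FALSE)
  means <- sample_means(table)
  keep <- unique(means$feature_id[means$mean_abundance >= min_abundance])
  if (length(keep) < 2L) {
    stop("fewer than 2 features pass the abundance gate", call. = FALSE)
  }
  m <- abundance_matrix(table)
  m <- m[rownames(m) %in% keep, , drop = FALSE]
  if (scale == "log") m <- log10(m + 1)
  # observations = columns; center per feature (prcomp centers per variable)
  p <- prcomp(t(m), center = TRUE, scale. = FALSE)
  obs <- colnames(m)
  scores <- tibble::as_tibble(p$x)
  scores$observation <- obs
  scores$sample <- sub("\\.[0-9]+$", "", obs)
  scores$replicate <- as.integer(sub("^.*\\.", "", obs))
  ev <- p$sdev^2 / sum(p$sdev^2)
  structure(
    list(scores = scores, loadings = p$rotation,
         explained_variance = ev, n_features = nrow(m), scale = scale),
    class = "metabolome_pca"
  )
}

#' Scatter plot of the first two principal components
#'
#' @param pca A `metabolome_pca` from [pca_features()].
#' @return A ggplot object.
#' @export
plot_pca <- function(pca) {
  stopifnot(inherits(pca, "metabolome_pca"))
  ev <- pca$explained_variance
  ggplot2::ggplot(pca$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$sample)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ev[2]),
      colour = "sample"
    ) +
    ggplot2::theme_bw()
}
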