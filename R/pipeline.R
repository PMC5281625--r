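# End-to-end orchestration: configuration, stage execution and report
# writing. The R functions are the interface; inst/scripts/run_pipeline.R
# is a thin shell wrapper over run_pipeline().

#' Read packaged or user gene-frequency and chemistry tables
#'
#' `read_gene_frequencies()` reads a long table `gene`, `category`,
#' `sample`, `hits_per_million`; `read_site_chemistry()` reads produced-
#' water chemistry with one row per analyte and one column per system.
#'
#' @param path File path; defaults to the packaged pipeline dataset.
#' @return A tibble.
#' @export
read_gene_frequencies <- function(path = micdiag_example("pipeline_gene_frequencies.tsv")) {
  tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_gene_frequencies
#' @export
read_site_chemistry <- function(path = micdiag_example("pipeline_site_chemistry.tsv")) {
  tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' Read gene counts and metagenome sizes from delimited text
#'
#' Gene counts: columns `gene`, `sample`, `count`. Sizes: columns
#' `sample`, `total_reads`, `total_bases`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_gene_counts <- function(path) {
  raw <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  stopifnot(all(c("gene", "sample", "count") %in% names(raw)))
  raw
}

#' @rdname read_gene_counts
#' @export
read_metagenome_sizes <- function(path) {
  raw <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  stopifnot(all(c("sample", "total_reads", "total_bases") %in% names(raw)))
  raw
}

#' Write a compound library to delimited text
#'
#' Writes the interface columns understood by [read_compound_library()];
#' generator ground-truth columns are dropped.
#'
#' @param library Library tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_compound_library <- function(library, path) {
  cols <- c("compound_id", "name", "formula", "source_db", "db_priority",
            "pathway_ids", paste0("d", 1:6), "reference_rt")
  out <- as.data.frame(library)[, cols]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a pipeline run configuration
#'
#' Collects every threshold of the end-to-end comparison workflow with its
#' standard default: 6 ppm / 0.25 min alignment tolerances, the 1,000 i.u.
#' abundance floor, the 45% retention-time rejection, the targeted-screen
#' gates (2 ppm / 10%), the differential-feature gates (10,000 i.u.,
#' ratio 5), the 3-fold similarity window, and the top-200 identified
#' ratio.
#'
#' @param system_map Named sample -> system map.
#' @param mass_tol_ppm,rt_tol_min Alignment tolerances.
#' @param min_abundance_iu Feature abundance floor, i.u.
#' @param rt_reject_fraction Annotation RT rejection fraction.
#' @param screen_tol_ppm,screen_rt_fraction Targeted-screen gates.
#' @param diff_min_abundance,diff_min_ratio Differential-feature gates.
#' @param similar_fold Similarity fold window.
#' @param top_n Top-N for the identified:non-identified ratio.
#' @param iu_per_ion Instrument units per detected ion.
#' @param seed Seed for any stochastic step.
#' @return A list of class `run_config`.
#' @export
run_config <- function(system_map = default_system_map,
                       mass_tol_ppm = 6, rt_tol_min = 0.25,
                       min_abundance_iu = 1000, rt_reject_fraction = 0.45,
                       screen_tol_ppm = 2, screen_rt_fraction = 0.10,
                       diff_min_abundance = 10000, diff_min_ratio = 5,
                       similar_fold = 3, top_n = 200,
                       iu_per_ion = 12.5, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(all(vapply(
    cfg[c("mass_tol_ppm", "rt_tol_min", "min_abundance_iu",
          "rt_reject_fraction", "screen_tol_ppm", "screen_rt_fraction",
          "diff_min_abundance", "diff_min_ratio", "similar_fold", "top_n")],
    function(x) is.numeric(x) && x > 0, logical(1))))
  structure(cfg, class = "run_config")
}

#' Run the full metabolome + metagenome comparison pipeline
#'
#' Executes the stages in order - abundance filtering and shot-noise QC,
#' library annotation with RT gating, targeted succinate screening,
#' system-level metabolome statistics (RN, differential features, ratio
#' distribution, identified ratios, PCA), and metagenome TEA arithmetic
#' (per-million normalization, pathway calls, cell fractions) - and
#' returns all stage results plus a machine-readable summary. When `out`
#' is given, per-stage tables and a JSON summary are written there.
#'
#' @param table Aligned `feature_table` (or path to one).
#' @param library Compound library tibble (or path).
#' @param standards RT calibration standards (or path), optional.
#' @param screen_series_list List of `homolog_series` for the targeted
#'   screen, optional.
#' @param bins,gene_counts,sizes Metagenome inputs (tibbles or paths),
#'   optional.
#' @param config A [run_config()].
#' @param out Optional output directory.
#' @return A list of class `micdiag_run` with stage results and `summary`.
#' @export
run_pipeline <- function(table, library = NULL, standards = NULL,
                         screen_series_list = NULL, bins = NULL,
                         gene_counts = NULL, sizes = NULL,
                         config = run_config(), out = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(table)) table <- read_feature_table(table)
  if (n_features(table) == 0L) {
    stop("stage 'process': feature table is empty", call. = FALSE)
  }
  if (is.character(library)) library <- read_compound_library(library)
  if (is.character(standards)) {
    standards <- read.delim(standards, stringsAsFactors = FALSE)
  }
  if (is.character(bins)) bins <- read_bin_table(bins)
  if (is.character(gene_counts)) gene_counts <- read_gene_counts(gene_counts)
  if (is.character(sizes)) sizes <- read_metagenome_sizes(sizes)

  res <- list(config = config)
  n_input <- n_features(table)

  # process: abundance filtering + QC
  filtered <- filter_low_abundance(table, config$min_abundance_iu)
  res$qc <- qc_shot_noise(filtered, iu_per_ion = config$iu_per_ion,
                          min_mean_iu = config$min_abundance_iu)
  res$table <- filtered

  # annotate
  if (!is.null(library)) {
    rt_model <- if (!is.null(standards)) fit_rt_model(standards) else NULL
    res$rt_model <- rt_model
    res$annotations <- match_features(
      filtered, library, mass_tol_ppm = config$mass_tol_ppm,
      rt_model = rt_model, rt_reject_fraction = config$rt_reject_fraction
    )
    means <- sample_means(filtered)
    tot <- tapply(means$mean_abundance, means$feature_id, sum)
    res$pathways <- map_pathways(res$annotations, library, abundance = tot)
  }

  # targeted screen
  if (!is.null(screen_series_list)) {
    res$detections <- screen_series(
      filtered, screen_series_list,
      mass_tol_ppm = config$screen_tol_ppm,
      rt_tol_fraction = config$screen_rt_fraction
    )
  }

  # metabolome statistics
  sys <- system_sums(filtered, config$system_map)
  systems <- unique(unname(config$system_map))
  res$system_sums <- sys
  res$differential <- differential_features(
    sys, systems = systems,
    min_abundance = config$diff_min_abundance,
    min_ratio = config$diff_min_ratio
  )
  res$ratio_distribution <- ratio_distribution(sys, systems = systems,
                                               fold = config$similar_fold)
  res$rn <- dplyr::bind_rows(lapply(table$sample_names, function(s) {
    rn_statistic(filtered, s,
                 annotations = res$annotations, library = library)
  }))
  if (!is.null(res$annotations)) {
    res$id_ratios <- lapply(setNames(nm = filtered$sample_names), function(s) {
      n_avail <- n_features(filtered)
      id_ratio_top_n(filtered, res$annotations, s,
                     n = min(config$top_n, n_avail))
    })
  }
  res$pca <- tryCatch(
    pca_features(filtered, min_abundance = config$diff_min_abundance),
    error = function(e) NULL
  )

  # metagenome TEA arithmetic
  if (!is.null(bins) && !is.null(sizes)) {
    defs <- default_pathway_definitions()
    res$pathway_calls <- lapply(setNames(nm = bins$bin_id), function(b) {
      genes <- bins$genes[[match(b, bins$bin_id)]]
      vapply(defs[c("denitrification", "sulfate_reduction")],
             function(d) call_pathway(genes, d)$present, logical(1))
    })
    res$cell_fractions <- lapply(
      setNames(nm = c("denitrification", "sulfate_reduction")),
      function(pw) {
        vapply(sizes$sample, function(s) {
          cell_fraction(bins, defs[[pw]], s,
                        sizes$total_bases[sizes$sample == s])$percent
        }, numeric(1))
      }
    )
  }
  if (!is.null(gene_counts) && !is.null(sizes)) {
    res$gene_frequencies <- per_million(gene_counts, sizes)
  }

  res$summary <- list(
    n_features_input = n_input,
    n_features_retained = n_features(filtered),
    n_features_removed = attr(filtered, "n_removed"),
    qc_consistent_fraction = res$qc$consistent_fraction,
    n_annotated = if (!is.null(res$annotations)) {
      sum(res$annotations$accepted)
    } else NA_integer_,
    n_detections = if (!is.null(res$detections)) {
      nrow(res$detections)
    } else NA_integer_,
    differential_counts = res$differential[
      grep("_enriched_count$", names(res$differential))],
    fraction_similar = res$ratio_distribution$fraction_similar,
    rn_percent = setNames(res$rn$rn_percent, res$rn$sample),
    cell_fractions = res$cell_fractions,
    thresholds = unclass(config)[setdiff(names(config), "system_map")],
    seed = config$seed
  )
  class(res) <- "micdiag_run"

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(filtered, file.path(out, "features_filtered.tsv"))
    write.table(as.data.frame(res$qc$measurements),
                file.path(out, "qc_shot_noise.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$annotations)) {
      write.table(as.data.frame(res$annotations),
                  file.path(out, "annotations.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(res$detections)) {
      write.table(as.data.frame(res$detections),
                  file.path(out, "detections.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(as.data.frame(res$rn), file.path(out, "rn_statistic.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(res$differential$per_feature),
                file.path(out, "differential_features.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(res$summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.micdiag_run <- function(x, ...) {
  s <- x$summary
  cat("<micdiag_run>\n")
  cat("  features: ", s$n_features_input, " in, ", s$n_features_retained,
      " retained (floor ", x$config$min_abundance_iu, " i.u.)\n", sep = "")
  cat("  shot-noise consistent: ",
      sprintf("%.1f%%", 100 * s$qc_consistent_fraction), "\n", sep = "")
  if (!is.na(s$n_annotated)) {
    cat("  accepted annotations: ", s$n_annotated, "\n", sep = "")
  }
  dc <- unlist(s$differential_counts)
  cat("  differential features: ",
      paste(names(dc), dc, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  RN (%): ", paste(names(s$rn_percent),
                          sprintf("%.1f", s$rn_percent),
                          sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
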