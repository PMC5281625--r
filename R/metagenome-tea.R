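# Downstream arithmetic on metagenome annotation products: per-million
# gene-frequency normalization, fold comparisons, pathway presence calls on
# genome bins, and coverage-based community-fraction estimation.

#' Default terminal-electron-acceptor pathway definitions
#'
#' Each pathway is a list of alternative-gene groups; a genome bin carries
#' the pathway when *every* group intersects its gene annotations. The
#' defaults are marker-gene based: denitrification requires a nitrate
#' reductase (narG or napA), a nitrite reductase (nirS or nirK), nitric
#' oxide reductase (norB) and nitrous oxide reductase (nosZ); dissimilatory
#' sulfate reduction requires both subunits of the dissimilatory sulfite
#' reductase (dsrA and dsrB).
#'
#' @return Named list of pathway definitions (lists of character vectors).
#' @export
default_pathway_definitions <- function() {
  list(
    denitrification = list(
      c("narG", "napA"), c("nirS", "nirK"), "norB", "nosZ"
    ),
    sulfate_reduction = list("dsrA", "dsrB"),
    methanogenesis = list("mcrA"),
    aerobic_hydrocarbon = list(c("alkB", "xylM", "todC1", "nahAc")),
    anaerobic_hydrocarbon = list(c("assA", "bssA", "nmsA"))
  )
}

#' Read a genome-bin table from delimited text
#'
#' Tab-separated columns: `bin_id`, `site`, `contig_count`,
#' `total_length_bp`, one `coverage_<sample>` column per sample,
#' `gene_annotations` (semicolon-joined gene labels), `recruitment_label`.
#'
#' @param path File path.
#' @return Tibble with a `genes` list-column and one `coverage_*` column
#'   per sample.
#' @export
read_bin_table <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("bin_id", "site", "total_length_bp", "gene_annotations")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("bin table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bins <- tibble::as_tibble(raw)
  bins$genes <- lapply(strsplit(as.character(bins$gene_annotations), ";"),
                       function(x) x[nzchar(x)])
  bins
}

#' Normalize gene read counts to hits per million reads
#'
#' @param counts Tibble with columns `gene`, `sample`, `count`.
#' @param sizes Tibble with columns `sample`, `total_reads` (> 0).
#' @return Tibble `gene`, `sample`, `hits_per_million`.
#' @export
per_million <- function(counts, sizes) {
  counts <- tibble::as_tibble(counts)
  sizes <- tibble::as_tibble(sizes)
  stopifnot(all(c("gene", "sample", "count") %in% names(counts)),
            all(c("sample", "total_reads") %in% names(sizes)))
  missing <- setdiff(unique(counts$sample), sizes$sample)
  if (length(missing)) {
    stop("no metagenome size for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(sizes$total_reads <= 0)) {
    stop("metagenome sizes must be > 0", call. = FALSE)
  }
  total <- sizes$total_reads[match(counts$sample, sizes$sample)]
  tibble::tibble(
    gene = counts$gene, sample = counts$sample,
    hits_per_million = counts$count / total * 1e6
  )
}

#' Fold comparison of gene-family frequencies between sample groups
#'
#' Sums the per-million frequencies of a gene family within each sample,
#' then compares group A against group B either as a ratio of group means
#' or as per-sample pairwise ratios (samples paired in the order given).
#' A zero denominator yields `Inf` with `infinite = TRUE`, not an error.
#'
#' @param freqs Frequency tibble: `gene`, `sample`, `hits_per_million`.
#' @param gene_family Character vector of gene labels (non-empty).
#' @param group_a,group_b Sample names of the two groups.
#' @param aggregate `"mean"` (ratio of group means) or `"per_sample"`.
#' @return Tibble with `ratio` and `infinite` (one row for `"mean"`, one
#'   per sample pair for `"per_sample"`).
#' @export
fold_comparison <- function(freqs, gene_family, group_a, group_b,
                            aggregate = c("mean", "per_sample")) {
  aggregate <- match.arg(aggregate)
  freqs <- tibble::as_tibble(freqs)
  fam <- freqs[freqs$gene %in% gene_family, , drop = FALSE]
  if (nrow(fam) == 0L) {
    stop("gene family not present in the frequency table", call. = FALSE)
  }
  tot <- function(s) sum(fam$hits_per_million[fam$sample == s])
  a <- vapply(group_a, tot, numeric(1))
  b <- vapply(group_b, tot, numeric(1))
  if (aggregate == "mean") {
    r <- mean(a) / mean(b)
    tibble::tibble(comparison = "mean", ratio = r,
                   infinite = is.infinite(r))
  } else {
    stopifnot(length(group_a) == length(group_b))
    r <- a / b
    tibble::tibble(
      comparison = paste(group_a, group_b, sep = "/"),
      ratio = unname(r), infinite = is.infinite(unname(r))
    )
  }
}

#' Call pathway presence on a genome bin
#'
#' @param genes Character vector of a bin's gene annotations (or a bin row
#'   from [read_bin_table()]).
#' @param definition One pathway definition: list of alternative-gene
#'   groups, all of which must be satisfied.
#' @return List: `present`, `satisfied_groups`, `missing_groups` (each
#'   group rendered as a `|`-joined label).
#' @export
call_pathway <- function(genes, definition) {
  if (is.list(genes) && !is.null(genes$genes)) genes <- genes$genes[[1]]
  sat <- vapply(definition, function(group) any(group %in% genes), logical(1))
  labels <- vapply(definition, paste, character(1), collapse = "|")
  list(
    present = all(sat),
    satisfied_groups = labels[sat],
    missing_groups = labels[!sat]
  )
}

#' Coverage-based estimate of the community fraction carrying a pathway
#'
#' A genome bin's read share in a sample is its mean coverage times its
#' length, divided by the total bases sequenced in that sample's
#' metagenome. Summing read shares over all pathway-positive bins estimates
#' the fraction of cells in the community that carry the pathway. Because
#' the denominator is the whole metagenome (not just binned reads),
#' fractions over all bins need not reach 100% when binning is incomplete.
#'
#' @param bins Bin tibble from [read_bin_table()] (needs `total_length_bp`,
#'   a `coverage_<sample>` column, and a `genes` list-column).
#' @param definition Pathway definition (see
#'   [default_pathway_definitions()]).
#' @param sample Sample name (selects `coverage_<sample>`).
#' @param total_bases Total bases sequenced in that sample's metagenome.
#' @return List: `percent`, and `per_bin` tibble of positive bins with
#'   their contributions (percentage points).
#' @export
cell_fraction <- function(bins, definition, sample, total_bases) {
  stopifnot(total_bases > 0)
  cov_col <- paste0("coverage_", sample)
  if (!cov_col %in% names(bins)) {
    stop("bin table has no coverage column for sample '", sample, "'",
         call. = FALSE)
  }
  if (anyNA(bins[[cov_col]])) {
    bad <- bins$bin_id[is.na(bins[[cov_col]])][1]
    stop("bin '", bad, "' is missing coverage for sample '", sample, "'",
         call. = FALSE)
  }
  positive <- vapply(bins$genes, function(g) {
    call_pathway(g, definition)$present
  }, logical(1))
  contrib <- bins[[cov_col]] * bins$total_length_bp / total_bases * 100
  per_bin <- tibble::tibble(
    bin_id = bins$bin_id[positive],
    coverage = bins[[cov_col]][positive],
    total_length_bp = bins$total_length_bp[positive],
    percent = contrib[positive]
  )
  list(percent = sum(contrib[positive]), per_bin = per_bin)
}
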