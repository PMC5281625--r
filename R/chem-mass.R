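# Elemental formula arithmetic: parsing, monoisotopic and average mass,
# ESI adduct conversion, ppm/mDa error, and nitrogen-rule parity.

the <- new.env(parent = emptyenv())

element_mass_table <- function() {
  if (is.null(the$elements)) {
    path <- system.file("extdata", "element_masses.tsv", package = "micdiag")
    the$elements <- read.delim(path, stringsAsFactors = FALSE)
  }
  the$elements
}

#' Monoisotopic masses of the supported elements
#'
#' Named vector of monoisotopic (most-abundant isotope) atomic masses in Da,
#' read from the packaged constants table. Covers CHNOPS plus the halogens.
#'
#' @param kind `"monoisotopic"` (default) or `"average"` (standard atomic
#'   weights, used for solution-concentration conversions).
#' @return Named numeric vector, element symbol -> mass in Da.
#' @export
element_masses <- function(kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  tab <- element_mass_table()
  col <- if (kind == "monoisotopic") "monoisotopic_da" else "average_da"
  setNames(tab[[col]], tab$element)
}

#' Mass of the proton in Da, used for ESI adduct arithmetic
#'
#' The proton mass (1.007276 Da), not the hydrogen atom mass, is the correct
#' shift for singly protonated/deprotonated ions because the electron stays
#' behind (or is gained) on ionization.
#' @export
PROTON_MASS <- 1.007276467

#' Parse a molecular formula string
#'
#' Accepts Hill-style formulas of element symbols each followed by an
#' optional positive integer count, e.g. `"C6H10O4"`. No parentheses,
#' isotope labels or charges. Element symbols are restricted to the
#' packaged constants table (CHNOPS + halogens).
#'
#' @param text Formula string.
#' @return A named integer vector of element counts with class
#'   `"molecular_formula"`.
#' @export
#' @examples
#' parse_formula("C6H10O4")
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("malformed formula string: '", text, "'", call. = FALSE)
  }
  symbols <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  known <- element_mass_table()$element
  bad <- setdiff(symbols, known)
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 1L)) {
    off <- tokens[counts < 1L][1]
    stop("element count must be >= 1 (offending token: '", off, "')",
         call. = FALSE)
  }
  out <- tapply(counts, factor(symbols, levels = unique(symbols)), sum)
  out <- setNames(as.integer(out), names(out))
  structure(out, class = "molecular_formula")
}

#' Format a molecular formula back to a string
#'
#' Inverse of [parse_formula()]: elements in Hill order (C, H, then
#' alphabetical), count suffix omitted when 1.
#'
#' @param formula A `molecular_formula` or named count vector.
#' @return Formula string.
#' @export
format_formula <- function(formula) {
  counts <- as.integer(formula)
  syms <- names(formula)
  ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  idx <- match(ord, syms)
  paste0(ord, ifelse(counts[idx] == 1L, "", counts[idx]), collapse = "")
}

as_formula_counts <- function(formula) {
  if (is.character(formula)) parse_formula(formula) else formula
}

#' Monoisotopic (exact) mass of a formula
#'
#' Sum of most-abundant-isotope atomic masses; matches printed experimental
#' masses of standards at 4 decimal places when the measurement is accurate.
#'
#' @param formula Formula string or parsed `molecular_formula`.
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("C6H10O4") # ethylsuccinic acid, 146.0579
monoisotopic_mass <- function(formula) {
  counts <- as_formula_counts(formula)
  masses <- element_masses("monoisotopic")
  sum(masses[names(counts)] * as.numeric(counts))
}

#' Average molecular mass of a formula
#'
#' Uses standard atomic weights; appropriate for bulk-solution quantities
#' such as converting mg/L to mM.
#'
#' @inheritParams monoisotopic_mass
#' @return Average molecular mass in g/mol.
#' @export
average_mass <- function(formula) {
  counts <- as_formula_counts(formula)
  masses <- element_masses("average")
  sum(masses[names(counts)] * as.numeric(counts))
}

#' Convert a solution concentration from mg/L to mM
#'
#' @param mg_per_l Concentration in mg/L.
#' @param formula Molecular formula of the solute (string or parsed), e.g.
#'   `"C2H4O2"` for acetic acid.
#' @return Concentration in mmol/L.
#' @export
#' @examples
#' mg_per_l_to_mm(311, "C2H4O2") # ~5.2 mM acetate
mg_per_l_to_mm <- function(mg_per_l, formula) {
  stopifnot(is.numeric(mg_per_l), all(mg_per_l >= 0))
  mg_per_l / average_mass(formula)
}

#' Neutral mass from a measured ion m/z
#'
#' Converts a singly charged ESI ion to its neutral mass. Supported adducts
#' are `"protonated"` ([M+H]+, positive mode) and `"deprotonated"`
#' ([M-H]-, negative mode).
#'
#' @param mz Measured m/z in Da.
#' @param mode `"positive"` or `"negative"`.
#' @param adduct Adduct label; defaults to the mode's standard adduct.
#' @return Neutral mass in Da.
#' @export
neutral_from_ion <- function(mz, mode = c("positive", "negative"),
                             adduct = NULL) {
  mode <- match.arg(mode)
  if (is.null(adduct)) {
    adduct <- if (mode == "positive") "protonated" else "deprotonated"
  }
  if (!adduct %in% c("protonated", "deprotonated")) {
    stop("unknown adduct label: '", adduct, "'", call. = FALSE)
  }
  shift <- if (adduct == "protonated") -PROTON_MASS else +PROTON_MASS
  out <- mz + shift
  if (any(out <= 0)) stop("m/z smaller than the adduct mass shift", call. = FALSE)
  out
}

#' Ion m/z from a neutral mass
#'
#' Inverse of [neutral_from_ion()].
#' @inheritParams neutral_from_ion
#' @param neutral_mass Neutral mass in Da.
#' @return Ion m/z in Da.
#' @export
ion_from_neutral <- function(neutral_mass, mode = c("positive", "negative"),
                             adduct = NULL) {
  mode <- match.arg(mode)
  if (is.null(adduct)) {
    adduct <- if (mode == "positive") "protonated" else "deprotonated"
  }
  if (!adduct %in% c("protonated", "deprotonated")) {
    stop("unknown adduct label: '", adduct, "'", call. = FALSE)
  }
  shift <- if (adduct == "protonated") +PROTON_MASS else -PROTON_MASS
  neutral_mass + shift
}

#' Signed mass error in ppm and mDa
#'
#' @param observed Observed mass, Da.
#' @param theoretical Theoretical mass, Da (> 0).
#' @return A list with components `ppm` and `mda`, both signed; vectorized.
#' @export
#' @examples
#' mass_error(146.0588, 146.05791)
mass_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  list(
    ppm = (observed - theoretical) / theoretical * 1e6,
    mda = (observed - theoretical) * 1e3
  )
}

#' Nitrogen-rule parity of a neutral mass
#'
#' Rounds the neutral monoisotopic mass to its nominal (integer) mass using
#' round-half-up and classifies it as odd or even. For even-electron CHNOPS
#' molecules, an odd nominal mass implies an odd number of nitrogen atoms
#' (the nitrogen rule). Above `mass_limit` (default 500 Da) the cumulative
#' mass defect makes simple rounding unreliable and the result is flagged.
#'
#' @param neutral_mass Neutral mass in Da (vectorized, > 0).
#' @param mass_limit Mass above which the parity call is flagged unreliable.
#' @return A tibble with columns `neutral_mass`, `nominal_mass`, `is_odd`,
#'   `implied_odd_nitrogen`, `unreliable`.
#' @export
#' @examples
#' nitrogen_parity(146.0579)
nitrogen_parity <- function(neutral_mass, mass_limit = 500) {
  stopifnot(all(neutral_mass > 0))
  nominal <- floor(neutral_mass + 0.5) # round-half-up
  is_odd <- nominal %% 2 == 1
  tibble::tibble(
    neutral_mass = neutral_mass,
    nominal_mass = as.integer(nominal),
    is_odd = is_odd,
    implied_odd_nitrogen = is_odd,
    unreliable = neutral_mass > mass_limit
  )
}

#' Ring-and-double-bond equivalents (degree of unsaturation)
#'
#' DBE = C + 1 + (N + P)/2 - (H + halogens)/2, treating phosphorus like
#' nitrogen (trivalent). A chemically plausible even-electron molecule has a
#' non-negative integer DBE; radical compositions have half-integer DBE and
#' fall outside the nitrogen rule's domain.
#'
#' @inheritParams monoisotopic_mass
#' @return Numeric DBE (may be half-integer for radical compositions).
#' @export
rdbe <- function(formula) {
  counts <- as_formula_counts(formula)
  g <- function(el) if (el %in% names(counts)) as.numeric(counts[[el]]) else 0
  halogens <- g("F") + g("Cl") + g("Br") + g("I")
  g("C") + 1 + (g("N") + g("P")) / 2 - (g("H") + halogens) / 2
}
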