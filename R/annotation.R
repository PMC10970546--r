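# Monoisotopic masses (Da) of the most abundant isotope of each element,
# CODATA/AME-derived values; enough coverage for small-molecule formulas.
.monoisotopic <- c(
  H = 1.00782503207, C = 12.0, N = 14.0030740048, O = 15.9949146196,
  S = 31.97207100, P = 30.97376163, Na = 22.9897692809, Cl = 34.96885268,
  K = 38.96370668, F = 18.99840322, Br = 78.9183371, I = 126.904473,
  Si = 27.9769265325, Se = 79.9165213, Fe = 55.9349375, Mg = 23.9850417,
  Ca = 39.96259098, Zn = 63.9291422, Cu = 62.9295975, B = 11.0093054,
  Li = 7.01600455
)

.electron_mass <- 0.000548579909

#' Parse a molecular formula
#'
#' Parses a Hill-style formula string (`Element(Count?)` repeated, e.g.
#' `"C2H7NO3S"`) into named element counts. An omitted count means 1; a
#' written count of zero, an unknown element symbol or trailing garbage is
#' an error reporting the character position.
#'
#' @param s Formula string.
#' @return Named integer vector of element counts, in order of appearance.
#' @examples
#' parse_formula("C2H7NO3S")
#' @export
parse_formula <- function(s) {
  if (!is.character(s) || length(s) != 1 || is.na(s) || nchar(s) == 0) {
    abort("Formula must be a single non-empty string.")
  }
  counts <- integer(0)
  pos <- 1L
  n <- nchar(s)
  while (pos <= n) {
    m <- regmatches(substr(s, pos, n),
                    regexec("^([A-Z][a-z]?)([0-9]*)", substr(s, pos, n)))[[1]]
    if (length(m) == 0 || m[1] == "") {
      abort(paste0("Formula parse error at position ", pos, " of '", s, "'."))
    }
    elem <- m[2]
    if (!elem %in% names(.monoisotopic)) {
      abort(paste0("Unknown element '", elem, "' at position ", pos,
                   " of '", s, "'."))
    }
    cnt_str <- m[3]
    cnt <- if (cnt_str == "") 1L else as.integer(cnt_str)
    if (cnt == 0L) {
      abort(paste0("Zero count for element '", elem, "' at position ", pos,
                   " of '", s, "'."))
    }
    counts[elem] <- (if (elem %in% names(counts)) counts[[elem]] else 0L) + cnt
    pos <- pos + nchar(elem) + nchar(cnt_str)
  }
  counts
}

#' Format element counts back into a formula string
#'
#' Inverse of [parse_formula()] up to element order: elements are emitted in
#' the order of the input vector, counts of 1 omitted.
#'
#' @param counts Named integer vector of element counts.
#' @return A formula string.
#' @export
format_formula <- function(counts) {
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Monoisotopic mass of a formula
#'
#' Sum of most-abundant-isotope atomic masses, the mass a high-resolution
#' TOF observes for the principal isotopologue of the neutral molecule.
#'
#' @param f A formula string or a named count vector from [parse_formula()].
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  if (length(f) == 0) return(0)
  missing <- setdiff(names(f), names(.monoisotopic))
  if (length(missing) > 0) {
    abort(paste0("No atomic mass for element(s): ",
                 paste(missing, collapse = ", ")))
  }
  sum(.monoisotopic[names(f)] * as.numeric(f))
}

#' Electrospray adduct registry
#'
#' The default single-charge adducts used to reconcile observed feature m/z
#' with neutral monoisotopic masses. Mass deltas are computed from atomic
#' masses with the electron mass accounted for (e.g. `[M+H]+` adds a proton,
#' 1.00727646 Da).
#'
#' @param polarity Optional filter, `"pos"` or `"neg"`.
#' @return A tibble with columns `adduct`, `polarity`, `charge`, `delta`
#'   (Da added to the neutral mass before dividing by charge).
#' @export
adduct_registry <- function(polarity = NULL) {
  mH <- .monoisotopic[["H"]]
  mO <- .monoisotopic[["O"]]
  mNa <- .monoisotopic[["Na"]]
  mC <- .monoisotopic[["C"]]
  me <- .electron_mass
  water <- 2 * mH + mO
  reg <- tibble::tribble(
    ~adduct, ~polarity, ~charge, ~delta,
    "[M+H]+", "pos", 1L, mH - me,
    "[M+Na]+", "pos", 1L, mNa - me,
    "[M+H-H2O]+", "pos", 1L, mH - me - water,
    "[M-H]-", "neg", 1L, -(mH - me),
    "[M+HCOO]-", "neg", 1L, mC + mH + 2 * mO + me,
    "[M-H-H2O]-", "neg", 1L, -(mH - me) - water
  )
  if (!is.null(polarity)) {
    .assert_mode(polarity)
    reg <- dplyr::filter(reg, .data$polarity == !!polarity)
  }
  reg
}

#' Theoretical ion m/z for a neutral mass under an adduct rule
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param adduct An adduct name from [adduct_registry()] or a one-row
#'   registry tibble.
#' @return m/z in Da per unit charge.
#' @examples
#' adduct_mz(monoisotopic_mass("C2H7NO3S"), "[M+Na]+")
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  if (is.character(adduct)) {
    reg <- adduct_registry()
    row <- reg[reg$adduct == adduct, ]
    if (nrow(row) != 1) abort(paste0("Unknown adduct '", adduct, "'."))
  } else {
    row <- adduct
  }
  mz <- (neutral_mass + row$delta) / row$charge
  if (any(mz <= 0)) abort("Adduct m/z must be positive.")
  mz
}

#' Annotate features against a compound library
#'
#' For every combination of feature, library compound and polarity-matched
#' adduct, records a hit when the observed m/z agrees with the theoretical
#' ion m/z within `tol_ppm`. Hits are accurate-mass-only annotations
#' (Metabolomics Standards Initiative level 3); orthogonal confirmation
#' (MS/MS, chromatographic review) is represented only by the pass-through
#' `verified` flag when present on the input.
#'
#' @param features A tibble with columns `feature_id`, `mz`, `mode` (plus
#'   anything else, carried along is `rt` when present).
#' @param library A compound library from [read_compound_library()].
#' @param adducts Adduct registry subset, default [adduct_registry()].
#' @param tol_ppm Matching tolerance in parts per million (default 20).
#' @return A tibble of hits sorted by |ppm| within feature: `feature_id`,
#'   `mz`, `rt`, `mode`, `compound`, `formula`, `adduct`, `theoretical_mz`,
#'   `ppm`, `best` (logical, best hit per feature), `msi_level`.
#' @export
annotate_features <- function(features, library, adducts = adduct_registry(),
                              tol_ppm = 20) {
  .assert_mode(features$mode)
  if (!"rt" %in% names(features)) features$rt <- NA_real_
  cand <- tidyr::crossing(
    dplyr::select(features, "feature_id", "mz", "rt", "mode"),
    dplyr::select(library, compound = "name", "formula",
                  neutral_mass = "monoisotopic_mass")
  ) |>
    dplyr::inner_join(adducts, by = c(mode = "polarity"),
                      relationship = "many-to-many") |>
    dplyr::mutate(
      theoretical_mz = (.data$neutral_mass + .data$delta) / .data$charge,
      ppm = 1e6 * (.data$mz - .data$theoretical_mz) / .data$theoretical_mz
    ) |>
    dplyr::filter(abs(.data$ppm) <= tol_ppm, .data$theoretical_mz > 0)
  cand |>
    dplyr::arrange(.data$feature_id, abs(.data$ppm)) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::mutate(best = dplyr::row_number() == 1L) |>
    dplyr::ungroup() |>
    dplyr::mutate(msi_level = 3L) |>
    dplyr::select("feature_id", "mz", "rt", "mode", "compound", "formula",
                  "adduct", "theoretical_mz", "ppm", "best", "msi_level")
}

#' Group annotation hits by compound
#'
#' One compound can claim several features (different adducts of the same
#' molecule); this summarises hits per distinct compound. By default only
#' each feature's best (smallest |ppm|) hit counts as its identification,
#' so one feature contributes one compound; set `best_only = FALSE` to
#' count every candidate hit.
#'
#' @param hits Output of [annotate_features()].
#' @param best_only Count only best-per-feature hits (default `TRUE`).
#' @return A tibble with one row per distinct compound: `compound`,
#'   `n_features`, `features` (semicolon-joined feature ids), `adducts`.
#' @export
distinct_compounds <- function(hits, best_only = TRUE) {
  if (best_only && nrow(hits) > 0) hits <- dplyr::filter(hits, .data$best)
  if (nrow(hits) == 0) {
    return(tibble::tibble(compound = character(), n_features = integer(),
                          features = character(), adducts = character()))
  }
  hits |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(
      n_features = dplyr::n_distinct(.data$feature_id),
      features = paste(unique(.data$feature_id), collapse = ";"),
      adducts = paste(unique(.data$adduct), collapse = ";"),
      .groups = "drop"
    )
}
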