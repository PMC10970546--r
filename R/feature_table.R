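#' Read an LC-MS feature table
#'
#' Reads a delimited text file of molecular features (one row per feature)
#' into the tidy feature-table format used throughout the package: the
#' columns `feature_id`, `mz`, `rt`, `mode` followed by one numeric intensity
#' column per sample. Feature ids follow the `"mz;rt"` convention used in
#' printed variable lists, so published tables can be ingested verbatim.
#'
#' Empty cells become `NA` (the missing marker); a literal `0` is a valid
#' measured intensity and is kept distinct from missing.
#'
#' @param path Path to a delimited text file. The header row must contain
#'   `feature_id`, `mz`, `rt`, then one column per sample. Lines starting
#'   with `#` are ignored.
#' @param mode Ionization polarity of the acquisition, `"pos"` or `"neg"`.
#' @param delim Field delimiter: `"tab"` (default) or `"comma"`.
#' @return A tibble with columns `feature_id`, `mz`, `rt`, `mode` and one
#'   numeric column per sample.
#' @seealso [write_feature_table()], [read_sample_sheet()]
#' @export
read_feature_table <- function(path, mode, delim = c("tab", "comma")) {
  .assert_mode(mode)
  delim <- match.arg(delim)
  raw <- .read_delim_chr(path, delim)
  need <- c("feature_id", "mz", "rt")
  if (!all(need %in% names(raw))) {
    abort(paste0("Feature table ", path, " must have columns: ",
                 paste(need, collapse = ", ")))
  }
  dup <- raw$feature_id[duplicated(raw$feature_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicated feature id(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  sample_ids <- setdiff(names(raw), need)
  if (anyDuplicated(sample_ids)) {
    abort("Duplicated sample column names in feature table.")
  }
  out <- tibble::tibble(
    feature_id = raw$feature_id,
    mz = .to_num(raw$mz, "mz", path),
    rt = .to_num(raw$rt, "rt", path),
    mode = mode
  )
  for (s in sample_ids) {
    out[[s]] <- .to_num(raw[[s]], s, path)
  }
  validate_feature_table(out)
}

#' Write a feature table to tab-separated text
#'
#' Writes the table with a `#`-prefixed header comment recording the package
#' version and any parameters, so outputs are self-describing. Numeric
#' values use a shortest round-trip representation: writing then reading
#' reproduces intensities bit-exactly.
#'
#' @param x A feature table (see [read_feature_table()]).
#' @param path Output path.
#' @param params Optional named character vector recorded in the header.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, params = NULL) {
  validate_feature_table(x)
  out <- dplyr::select(x, -"mode")
  .write_tsv_commented(out, path, params = c(mode = x$mode[1], params))
}

#' Read a sample sheet
#'
#' The sample sheet declares, for every injection, its role in the run:
#' `biological` (a study sample with subject and timepoint), `qc_pool`
#' (pooled QC re-injected through the sequence), `qc_cond` (leading
#' column-conditioning QCs, excluded from all statistics) or `blank`.
#'
#' @param path Delimited text file with columns `sample_id`, `role`,
#'   `subject`, `timepoint`, `injection_order`.
#' @param delim Field delimiter: `"tab"` or `"comma"`.
#' @return A validated tibble.
#' @export
read_sample_sheet <- function(path, delim = c("tab", "comma")) {
  delim <- match.arg(delim)
  raw <- .read_delim_chr(path, delim)
  need <- c("sample_id", "role", "subject", "timepoint", "injection_order")
  if (!all(need %in% names(raw))) {
    abort(paste0("Sample sheet must have columns: ",
                 paste(need, collapse = ", ")))
  }
  out <- tibble::tibble(
    sample_id = raw$sample_id,
    role = raw$role,
    subject = dplyr::na_if(raw$subject, ""),
    timepoint = dplyr::na_if(raw$timepoint, ""),
    injection_order = as.integer(.to_num(raw$injection_order,
                                         "injection_order", path))
  )
  validate_sample_sheet(out)
}

#' @rdname read_sample_sheet
#' @param x A sample sheet tibble.
#' @param params Optional named character vector recorded in the header.
#' @export
write_sample_sheet <- function(x, path, params = NULL) {
  validate_sample_sheet(x)
  .write_tsv_commented(x, path, params = params)
}

#' Validate a feature table
#'
#' Checks the in-memory contract: unique feature and sample ids, positive
#' `mz`, non-negative `rt`, and non-negative (or missing) intensities.
#'
#' @param x A feature-table tibble.
#' @return `x`, invisibly usable (returned unchanged) when valid.
#' @export
validate_feature_table <- function(x) {
  if (!all(.feature_meta_cols %in% names(x))) {
    abort(paste0("A feature table needs columns: ",
                 paste(.feature_meta_cols, collapse = ", ")))
  }
  dup <- x$feature_id[duplicated(paste(x$mode, x$feature_id))]
  if (length(dup) > 0) {
    abort(paste0("Duplicated feature id(s): ", paste(unique(dup), collapse = ", ")))
  }
  .assert_mode(x$mode)
  if (any(!is.finite(x$mz) | x$mz <= 0)) abort("All mz values must be > 0.")
  if (any(!is.finite(x$rt) | x$rt < 0)) abort("All rt values must be >= 0.")
  sc <- sample_columns(x)
  if (anyDuplicated(sc)) abort("Duplicated sample ids.")
  for (s in sc) {
    v <- x[[s]]
    if (!is.numeric(v)) abort(paste0("Intensity column ", s, " is not numeric."))
    if (any(v < 0, na.rm = TRUE)) {
      abort(paste0("Negative intensity in sample ", s, "."))
    }
  }
  x
}

#' Validate a sample sheet
#'
#' @param x A sample-sheet tibble.
#' @return `x` when valid; otherwise an error.
#' @export
validate_sample_sheet <- function(x) {
  roles <- c("biological", "qc_pool", "qc_cond", "blank")
  bad <- setdiff(unique(x$role), roles)
  if (length(bad) > 0) {
    abort(paste0("Unknown sample role(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(x$sample_id)) abort("Duplicated sample_id in sheet.")
  if (anyDuplicated(x$injection_order)) abort("Injection orders must be unique.")
  if (any(x$injection_order < 1)) abort("Injection orders must be positive.")
  bio <- x$role == "biological"
  if (any(is.na(x$subject[bio]) | is.na(x$timepoint[bio]))) {
    abort("Every biological sample needs a subject and a timepoint.")
  }
  if (any(!is.na(x$subject[!bio]) | !is.na(x$timepoint[!bio]))) {
    abort("QC/blank samples must not carry subject or timepoint.")
  }
  x
}

#' Sample (intensity) column names of a feature table
#'
#' @param x A feature table.
#' @return Character vector of sample ids.
#' @export
sample_columns <- function(x) setdiff(names(x), .feature_meta_cols)

#' Extract the intensity matrix of a feature table
#'
#' @param x A feature table.
#' @param samples Optional character vector restricting/ordering columns.
#' @return A numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns.
#' @export
intensity_matrix <- function(x, samples = NULL) {
  sc <- samples %||% sample_columns(x)
  m <- as.matrix(dplyr::select(x, dplyr::all_of(sc)))
  rownames(m) <- x$feature_id
  m
}

#' Subject pairing between two timepoints
#'
#' Derives the paired design for one comparison: each subject must appear
#' exactly once at each of the two timepoints among biological samples.
#'
#' @param samples A sample sheet.
#' @param t_early,t_late Timepoint labels (e.g. `"T0"`, `"T28"`).
#' @return A tibble with columns `subject`, `sample_early`, `sample_late`.
#' @export
sample_pairs <- function(samples, t_early, t_late) {
  bio <- dplyr::filter(samples, .data$role == "biological",
                       .data$timepoint %in% c(t_early, t_late))
  counts <- bio |>
    dplyr::count(.data$subject, .data$timepoint) |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "n",
                       values_fill = 0L)
  for (tp in c(t_early, t_late)) {
    if (!tp %in% names(counts)) counts[[tp]] <- 0L
    bad <- counts$subject[counts[[tp]] != 1L]
    if (length(bad) > 0) {
      abort(paste0("Pairing error: subject(s) ", paste(bad, collapse = ", "),
                   " do not appear exactly once at ", tp, "."))
    }
  }
  early <- dplyr::filter(bio, .data$timepoint == t_early)
  late <- dplyr::filter(bio, .data$timepoint == t_late)
  tibble::tibble(
    subject = early$subject,
    sample_early = early$sample_id,
    sample_late = late$sample_id[match(early$subject, late$subject)]
  )
}

#' Read a compound library
#'
#' Loads a table of candidate metabolites (name, molecular formula, HMDB
#' class and superclass). Formulas are parsed eagerly so malformed records
#' fail at load time, naming the offending compound.
#'
#' @param path Delimited text file with columns `name`, `formula`, `class`,
#'   `superclass`.
#' @param delim Field delimiter: `"tab"` or `"comma"`.
#' @return A tibble with the input columns plus `monoisotopic_mass` (Da).
#' @export
read_compound_library <- function(path, delim = c("tab", "comma")) {
  delim <- match.arg(delim)
  raw <- .read_delim_chr(path, delim)
  if (nrow(raw) == 0) {
    warn(paste0("Compound library ", path, " is empty."))
    return(tibble::tibble(name = character(), formula = character(),
                          class = character(), superclass = character(),
                          monoisotopic_mass = numeric()))
  }
  need <- c("name", "formula", "class", "superclass")
  if (!all(need %in% names(raw))) {
    abort(paste0("Compound library must have columns: ",
                 paste(need, collapse = ", ")))
  }
  if (anyDuplicated(raw$name)) abort("Compound names must be unique.")
  mono <- purrr::map2_dbl(raw$formula, raw$name, function(f, nm) {
    tryCatch(monoisotopic_mass(f),
             error = function(e) abort(paste0("Compound '", nm, "': ",
                                              conditionMessage(e))))
  })
  tibble::tibble(name = raw$name, formula = raw$formula, class = raw$class,
                 superclass = raw$superclass, monoisotopic_mass = mono)
}

#' Bundled 18-metabolite osteoarthritis serum library
#'
#' The compound library shipped with the package: 18 serum metabolites
#' identified in an MIA-induced rat osteoarthritis time course, with their
#' molecular formulas and HMDB taxonomy.
#'
#' @return A compound-library tibble (see [read_compound_library()]).
#' @export
oa_compound_library <- function() {
  read_compound_library(system.file("extdata", "oa18_compounds.tsv",
                                    package = "pairomics"))
}

#' Bundled selected-variable lists
#'
#' The published VIP-selected variable lists for the three paired
#' comparisons of the same study (positive/negative ESI, `"mz;rt"` ids and
#' VIP scores), usable as annotation inputs and worked examples.
#'
#' @param comparison One of `"T28"`, `"T56"`, `"T84"` (late timepoint of the
#'   paired comparison against T0).
#' @return A tibble with columns `feature_id`, `mz`, `rt`, `mode`,
#'   `vip`.
#' @export
oa_selected_variables <- function(comparison = c("T28", "T56", "T84")) {
  comparison <- match.arg(comparison)
  path <- system.file("extdata",
                      paste0("selected_variables_",
                             tolower(comparison), ".tsv"),
                      package = "pairomics")
  raw <- .read_delim_chr(path, "tab")
  tibble::tibble(
    feature_id = raw$feature_id,
    mz = .to_num(raw$mz, "mz", path),
    rt = .to_num(raw$rt, "rt", path),
    mode = .assert_mode(raw$mode),
    vip = .to_num(raw$vip, "vip", path)
  )
}

# -- internal io helpers ------------------------------------------------------

.read_delim_chr <- function(path, delim) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  ch <- if (delim == "tab") "\t" else ","
  readr::read_delim(path, delim = ch, comment = "#", na = character(),
                    col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE)
}

.to_num <- function(v, col, path) {
  out <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & v != "" & is.na(out))
  if (length(bad) > 0) {
    abort(paste0("Non-numeric value '", v[bad[1]], "' in column '", col,
                 "', data row ", bad[1], " of ", path, "."))
  }
  out[v == ""] <- NA_real_
  out
}

.write_tsv_commented <- function(x, path, params = NULL) {
  hdr <- paste0("# pairomics ",
                as.character(utils::packageVersion("pairomics")))
  if (length(params) > 0) {
    hdr <- paste0(hdr, " | ",
                  paste(names(params), unname(params), sep = "=",
                        collapse = " "))
  }
  writeLines(hdr, path)
  readr::write_tsv(x, path, na = "", append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}
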