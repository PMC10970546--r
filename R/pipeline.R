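#' Run the full paired biomarker-discovery analysis
#'
#' Orchestrates the end-to-end workflow for one paired comparison:
#' internal-standard normalization and QC-pool CV filtering per ionization
#' mode, paired volcano selection on the combined positive + negative
#' feature matrix, OPLS-DA on the volcano-selected subset (with
#' cross-validated Q2Y, CV-ANOVA and permutation validation), VIP-based
#' variable selection, and adduct annotation of the selected variables
#' against a compound library. Positive- and negative-mode features are
#' modelled jointly in one matrix (each mode normalized by its own internal
#' standard first), so the VIP ranking mixes both modes.
#'
#' The run is deterministic given `seed`.
#'
#' @param pos,neg Feature tables for the two ionization modes (they must
#'   share the sample sheet; either may be `NULL`).
#' @param samples The sample sheet.
#' @param library A compound library for annotation.
#' @param t_early,t_late Timepoint labels of the paired comparison.
#' @param istd Named character vector of internal-standard feature ids,
#'   e.g. `c(pos = "...", neg = "...")`.
#' @param cv_threshold QC CV% removal threshold (default 30).
#' @param fc_threshold,p_threshold Volcano thresholds (defaults 2, 0.05).
#' @param n_ortho Orthogonal component count or `"auto"`.
#' @param folds Cross-validation folds (default 7).
#' @param n_permutations Permutation-test iterations (default 1000).
#' @param top_n VIP rank cutoff for selection (default 30).
#' @param tol_ppm Annotation tolerance in ppm (default 20).
#' @param adducts Adduct registry (default [adduct_registry()]).
#' @param seed Integer seed driving fold assignment and permutations.
#' @param outdir Optional directory; when given, stage artifacts are
#'   written there as commented TSV files.
#' @return A list of class `paired_analysis` with elements `report` (tidy
#'   tibble of per-stage counts and diagnostics), `istd_reports`,
#'   `cv_filter`, `volcano`, `model`, `cv`, `cv_anova`, `permutation`,
#'   `vip`, `hits`, `compounds`, and `params`.
#' @export
run_paired_analysis <- function(pos, neg, samples, library,
                                t_early, t_late,
                                istd,
                                cv_threshold = 30,
                                fc_threshold = 2,
                                p_threshold = 0.05,
                                n_ortho = "auto",
                                folds = 7,
                                n_permutations = 1000,
                                top_n = 30,
                                tol_ppm = 20,
                                adducts = adduct_registry(),
                                seed = 1,
                                outdir = NULL) {
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(outdir)) {
        writeLines(paste0("FAILED at stage: ", name, "\n",
                          conditionMessage(e)),
                   file.path(outdir, "FAILED"))
      }
      abort(paste0("Pipeline failed at stage '", name, "': ",
                   conditionMessage(e)))
    })
  }

  tables <- list(pos = pos, neg = neg)
  tables <- tables[!vapply(tables, is.null, logical(1))]

  istd_reports <- list()
  filtered <- list()
  filter_results <- list()
  n_in <- n_retained <- integer(0)
  for (mode in names(tables)) {
    tab <- tables[[mode]]
    rep_m <- stage(paste0("istd_report_", mode),
                   istd_report(tab, samples, istd[[mode]]))
    norm <- stage(paste0("normalize_istd_", mode),
                  normalize_istd(tab, samples, istd[[mode]]))
    filt <- stage(paste0("cv_filter_", mode),
                  qc_cv_filter(norm, samples, cv_threshold))
    istd_reports[[mode]] <- rep_m
    filter_results[[mode]] <- filt
    filtered[[mode]] <- apply_cv_filter(norm, filt)
    n_in[mode] <- nrow(tab)
    n_retained[mode] <- nrow(filtered[[mode]])
  }

  combined <- stage("combine_modes", dplyr::bind_rows(filtered))
  volcano <- stage("volcano",
                   volcano_select(combined, samples, t_early, t_late,
                                  fc_threshold, p_threshold))
  sel <- dplyr::filter(volcano, .data$selected)
  if (nrow(sel) < 2) {
    abort(paste0("Pipeline failed at stage 'volcano': only ", nrow(sel),
                 " feature(s) selected; need at least 2 for OPLS-DA."))
  }

  opls_in <- stage("opls_matrix",
                   .paired_matrix(combined, samples, t_early, t_late, sel))
  model <- stage("opls_fit",
                 fit_oplsda(opls_in$x, opls_in$y, n_ortho = n_ortho,
                            folds = folds, seed = seed))
  cv <- stage("opls_cv",
              oplsda_cv(opls_in$x, opls_in$y, n_ortho = model$n_ortho,
                        folds = folds, seed = seed))
  anova <- stage("cv_anova", cv_anova(cv))
  perm <- stage("permutation",
                oplsda_permutation(opls_in$x, opls_in$y,
                                   n_ortho = model$n_ortho,
                                   n_iterations = n_permutations,
                                   folds = folds, seed = seed))
  vip <- stage("vip", select_vip(vip_scores(model, cv), top_n = top_n))

  sel_vars <- vip$variable[vip$selected]
  keys <- opls_in$key[match(sel_vars, opls_in$key$variable), ]
  hits <- stage("annotation",
                annotate_features(keys, library, adducts, tol_ppm))
  compounds <- stage("annotation", distinct_compounds(hits))

  report <- tibble::tibble(
    stage = c(
      paste0("input_", names(tables)),
      paste0("istd_slope_", names(tables)),
      paste0("cv_filter_retained_", names(tables)),
      "volcano_selected", "opls_r2y", "opls_q2y", "opls_n_ortho",
      "cv_anova_p", "permutation_p_q2", "vip_selected",
      "annotated_compounds"
    ),
    value = c(
      as.numeric(n_in),
      vapply(istd_reports, function(r) r$slope, numeric(1)),
      as.numeric(n_retained),
      nrow(sel), model$r2y, cv$q2, model$n_ortho,
      anova$p_value, perm$p_q2, length(sel_vars),
      nrow(compounds)
    )
  )

  out <- structure(list(
    report = report,
    istd_reports = istd_reports,
    cv_filter = dplyr::bind_rows(filter_results),
    volcano = volcano,
    model = model,
    cv = cv,
    cv_anova = anova,
    permutation = perm,
    vip = vip,
    hits = hits,
    compounds = compounds,
    params = list(t_early = t_early, t_late = t_late,
                  cv_threshold = cv_threshold, fc_threshold = fc_threshold,
                  p_threshold = p_threshold, folds = folds,
                  n_permutations = n_permutations, top_n = top_n,
                  tol_ppm = tol_ppm, seed = seed)
  ), class = "paired_analysis")

  if (!is.null(outdir)) {
    prm <- c(comparison = paste0(t_early, "-", t_late),
             seed = as.character(seed))
    .write_tsv_commented(report, file.path(outdir, "report.tsv"), prm)
    .write_tsv_commented(volcano, file.path(outdir, "volcano.tsv"), prm)
    .write_tsv_commented(vip, file.path(outdir, "vip.tsv"), prm)
    .write_tsv_commented(hits, file.path(outdir, "annotation_hits.tsv"), prm)
    .write_tsv_commented(perm$permuted,
                         file.path(outdir, "permutations.tsv"), prm)
  }
  out
}

#' @export
print.paired_analysis <- function(x, ...) {
  cat(sprintf("Paired analysis %s vs %s\n", x$params$t_early,
              x$params$t_late))
  print(x$report, n = nrow(x$report))
  invisible(x)
}

# samples x variables log10 matrix of the selected features for the two
# timepoints, plus the class vector and a variable -> feature key map
.paired_matrix <- function(features, samples, t_early, t_late, selection) {
  pairs <- sample_pairs(samples, t_early, t_late)
  rows <- match(paste(selection$mode, selection$feature_id),
                paste(features$mode, features$feature_id))
  feats <- features[rows, , drop = FALSE]
  cols <- c(pairs$sample_early, pairs$sample_late)
  m <- .impute_half_min(intensity_matrix(feats, cols))
  m[m <= 0] <- NA
  keep <- rowSums(is.na(m)) == 0
  m <- log10(m[keep, , drop = FALSE])
  feats <- feats[keep, , drop = FALSE]
  varname <- paste0(feats$mode, ":", feats$feature_id)
  x <- t(m)
  colnames(x) <- varname
  # zero-variance variables cannot enter the autoscaled model
  keep_var <- apply(x, 2, sd) > 0
  x <- x[, keep_var, drop = FALSE]
  feats <- feats[keep_var, , drop = FALSE]
  y <- factor(rep(c(t_early, t_late), each = nrow(pairs)),
              levels = c(t_early, t_late))
  key <- tibble::tibble(variable = colnames(x),
                        feature_id = feats$feature_id,
                        mz = feats$mz, rt = feats$rt, mode = feats$mode)
  list(x = x, y = y, key = key)
}

#' Read a pipeline configuration file
#'
#' Reads a YAML configuration describing one paired run: file paths
#' (`features_pos`, `features_neg`, `samples`, `library`), the comparison
#' (`t_early`, `t_late`), internal-standard ids (`istd_pos`, `istd_neg`)
#' and any stage parameters accepted by [run_paired_analysis()]. Referenced
#' files are checked for existence at load time.
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("features_pos", "features_neg", "samples", "library")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      abort(paste0("Config file references missing file: ", cfg[[f]]))
    }
  }
  cfg
}

#' Run a paired analysis from a configuration file
#'
#' @param config A path to a YAML file or a list from
#'   [read_pipeline_config()].
#' @param outdir Optional output directory passed to
#'   [run_paired_analysis()].
#' @return See [run_paired_analysis()].
#' @export
run_paired_analysis_config <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  pos <- if (!is.null(config$features_pos)) {
    read_feature_table(config$features_pos, "pos")
  }
  neg <- if (!is.null(config$features_neg)) {
    read_feature_table(config$features_neg, "neg")
  }
  run_paired_analysis(
    pos = pos, neg = neg,
    samples = read_sample_sheet(config$samples),
    library = read_compound_library(config$library),
    t_early = config$t_early, t_late = config$t_late,
    istd = c(pos = config$istd_pos, neg = config$istd_neg),
    cv_threshold = config$cv_threshold %||% 30,
    fc_threshold = config$fc_threshold %||% 2,
    p_threshold = config$p_threshold %||% 0.05,
    n_ortho = config$n_ortho %||% "auto",
    folds = config$folds %||% 7,
    n_permutations = config$n_permutations %||% 1000,
    top_n = config$top_n %||% 30,
    tol_ppm = config$tol_ppm %||% 20,
    seed = config$seed %||% 1,
    outdir = outdir
  )
}
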