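#' Internal-standard response report
#'
#' Control-chart style evaluation of the internal-standard channel across
#' the injection sequence: the per-injection area, the least-squares trend
#' of area against injection order with its slope t-test p-value, and the
#' within-sequence CV%. A flat trend (slope indistinguishable from 0)
#' indicates low intra-batch variability.
#'
#' @param features A feature table.
#' @param samples The matching sample sheet.
#' @param istd_id Feature id of the internal-standard channel.
#' @return A list of class `istd_report`: `areas` (tibble `sample_id`,
#'   `injection_order`, `area`), `slope`, `slope_se`, `slope_p`,
#'   `cv_percent`, `istd_id`.
#' @export
istd_report <- function(features, samples, istd_id) {
  area <- .istd_areas(features, samples, istd_id)
  if (nrow(area) < 3) abort("Need at least 3 injections for an ISTD report.")
  fit <- lm(area ~ injection_order, data = area)
  # a perfectly flat/linear channel is legitimate here; summary.lm warns
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(coef(fit)[2])
  slope_se <- if (nrow(sm) == 2) unname(sm[2, 2]) else NA_real_
  slope_p <- if (nrow(sm) == 2) unname(sm[2, 4]) else NA_real_
  structure(list(
    areas = area,
    slope = slope,
    slope_se = slope_se,
    slope_p = slope_p,
    cv_percent = 100 * sd(area$area) / mean(area$area),
    istd_id = istd_id
  ), class = "istd_report")
}

#' @export
print.istd_report <- function(x, ...) {
  cat("Internal-standard report for", x$istd_id, "\n")
  cat(sprintf("  %d injections; CV%% = %.2f\n", nrow(x$areas), x$cv_percent))
  cat(sprintf("  trend slope = %.4g (p = %.3g)\n", x$slope, x$slope_p))
  invisible(x)
}

#' Control chart of the internal-standard response
#'
#' @param report An [istd_report()].
#' @return A ggplot: area vs injection order with the fitted trend.
#' @export
plot_istd <- function(report) {
  ggplot2::ggplot(report$areas,
                  ggplot2::aes(x = .data$injection_order, y = .data$area)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "firebrick") +
    ggplot2::labs(x = "Injection order", y = "ISTD area",
                  title = paste("Internal standard", report$istd_id),
                  subtitle = sprintf("CV%% = %.1f, slope p = %.3g",
                                     report$cv_percent, report$slope_p)) +
    ggplot2::theme_minimal()
}

#' Normalize a feature table to its internal standard
#'
#' Adjusts every sample for the area of the internal-standard channel:
#' each sample's intensities are multiplied by
#' `median(ISTD area) / ISTD area of that sample`, so a sample whose ISTD
#' responded twice as strongly as typical has all intensities halved. The
#' operation is idempotent and leaves the ISTD channel constant.
#'
#' @param features A feature table.
#' @param samples The matching sample sheet.
#' @param istd_id Feature id of the internal-standard channel.
#' @return The normalized feature table.
#' @export
normalize_istd <- function(features, samples, istd_id) {
  area <- .istd_areas(features, samples, istd_id)
  bad <- area$sample_id[is.na(area$area) | area$area <= 0]
  if (length(bad) > 0) {
    abort(paste0("ISTD area missing or non-positive in sample(s): ",
                 paste(bad, collapse = ", ")))
  }
  ref <- median(area$area)
  out <- features
  for (i in seq_len(nrow(area))) {
    s <- area$sample_id[i]
    out[[s]] <- out[[s]] * (ref / area$area[i])
  }
  out
}

.istd_areas <- function(features, samples, istd_id) {
  row <- which(features$feature_id == istd_id)
  if (length(row) != 1) {
    abort(paste0("ISTD feature '", istd_id, "' not found in table."))
  }
  sc <- intersect(sample_columns(features), samples$sample_id)
  tibble::tibble(
    sample_id = sc,
    injection_order = samples$injection_order[match(sc, samples$sample_id)],
    area = unlist(features[row, sc], use.names = FALSE)
  ) |>
    dplyr::arrange(.data$injection_order)
}

#' QC-pool coefficient-of-variation filter
#'
#' Computes the per-feature CV% over pooled-QC injections (conditioning QCs
#' excluded) and flags features at or above the threshold for removal:
#' features whose analytical variability rivals biological effect sizes
#' carry no usable signal. Features missing in more than half of the QC
#' injections are removed as unquantifiable; otherwise the CV uses observed
#' values only. The CV uses the sample standard deviation (n - 1).
#'
#' @param features A feature table (normalize first: see
#'   [normalize_istd()]).
#' @param samples The matching sample sheet; needs >= 3 `qc_pool` samples.
#' @param threshold_percent Removal threshold; features with
#'   `CV% >= threshold_percent` are removed (default 30).
#' @return A tibble with one row per feature: `feature_id`, `mode`,
#'   `qc_cv_percent`, `n_qc`, `n_observed`, `retained`, `reason` (`NA`,
#'   `"cv"` or `"missing"`); the threshold is stored in the
#'   `"threshold_percent"` attribute.
#' @seealso [apply_cv_filter()]
#' @export
qc_cv_filter <- function(features, samples, threshold_percent = 30) {
  qc_ids <- samples$sample_id[samples$role == "qc_pool"]
  qc_ids <- intersect(sample_columns(features), qc_ids)
  if (length(qc_ids) < 3) {
    abort("Need at least 3 qc_pool samples for the CV filter.")
  }
  m <- intensity_matrix(features, qc_ids)
  n_obs <- rowSums(!is.na(m))
  cv <- rep(NA_real_, nrow(m))
  ok <- n_obs >= 2
  cv[ok] <- 100 * apply(m[ok, , drop = FALSE], 1, sd, na.rm = TRUE) /
    rowMeans(m[ok, , drop = FALSE], na.rm = TRUE)
  too_missing <- n_obs < length(qc_ids) / 2
  removed_cv <- !too_missing & !is.na(cv) & cv >= threshold_percent
  out <- tibble::tibble(
    feature_id = features$feature_id,
    mode = features$mode,
    qc_cv_percent = cv,
    n_qc = length(qc_ids),
    n_observed = n_obs,
    retained = !(too_missing | removed_cv),
    reason = dplyr::case_when(
      too_missing ~ "missing",
      removed_cv ~ "cv",
      .default = NA_character_
    )
  )
  attr(out, "threshold_percent") <- threshold_percent
  out
}

#' Apply a CV-filter result to a feature table
#'
#' @param features The feature table the filter was computed on.
#' @param filter_result Output of [qc_cv_filter()].
#' @return The feature table restricted to retained features.
#' @export
apply_cv_filter <- function(features, filter_result) {
  keep <- filter_result$feature_id[filter_result$retained]
  dplyr::filter(features, .data$feature_id %in% keep)
}
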