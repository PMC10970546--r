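#' Paired volcano-plot feature selection
#'
#' For each feature, computes the fold change between two timepoints (ratio
#' of means across biological samples, late over early) and a two-sided
#' paired t-test on log10-transformed intensities, pairing each subject's
#' two samples. A feature is selected when it clears both thresholds
#' two-sidedly: `FC >= fc_threshold` or `FC <= 1/fc_threshold`, and
#' `p < p_threshold`.
#'
#' Missing intensities are imputed per feature as half the minimum observed
#' positive intensity before testing (a standard proxy for
#' below-detection-limit values). Features whose paired log differences
#' have zero variance get `p = 0` when the common difference is nonzero and
#' `p = 1` otherwise, with `degenerate = TRUE`.
#'
#' @param features A feature table (QC-filtered and normalized upstream).
#' @param samples The matching sample sheet.
#' @param t_early,t_late Timepoint labels defining the comparison.
#' @param fc_threshold Fold-change threshold, applied symmetrically
#'   (default 2).
#' @param p_threshold Raw paired t-test p-value threshold (default 0.05); no
#'   multiple-testing correction is applied, by design.
#' @return A tibble with one row per feature: `feature_id`, `mode`, `mz`,
#'   `rt`, `fc`, `log2_fc`, `p_value`, `neg_log10_p`, `degenerate`,
#'   `excluded`, `selected`.
#' @export
volcano_select <- function(features, samples, t_early, t_late,
                           fc_threshold = 2, p_threshold = 0.05) {
  pairs <- sample_pairs(samples, t_early, t_late)
  n <- nrow(pairs)
  if (n < 3) abort("Need at least 3 subject pairs for the paired t-test.")

  early <- intensity_matrix(features, pairs$sample_early)
  late <- intensity_matrix(features, pairs$sample_late)
  early <- .impute_half_min(early)
  late <- .impute_half_min(late)

  mean_early <- unname(rowMeans(early))
  mean_late <- unname(rowMeans(late))
  excluded <- unname(mean_early <= 0 | mean_late <= 0 |
                       rowSums(early <= 0) > 0 | rowSums(late <= 0) > 0)
  if (any(excluded)) {
    warn(paste0(sum(excluded), " feature(s) with non-positive intensities ",
                "after imputation were excluded from the volcano test."))
  }
  fc <- mean_late / mean_early

  d <- log10(late) - log10(early)
  d[excluded, ] <- NA
  mean_d <- unname(rowMeans(d))
  sd_d <- unname(apply(d, 1, sd))
  tstat <- mean_d / (sd_d / sqrt(n))
  p <- 2 * pt(-abs(tstat), df = n - 1)
  degenerate <- !excluded & sd_d == 0
  p[degenerate] <- ifelse(mean_d[degenerate] == 0, 1, 0)

  out <- tibble::tibble(
    feature_id = features$feature_id,
    mode = features$mode,
    mz = features$mz,
    rt = features$rt,
    fc = ifelse(excluded, NA_real_, fc),
    log2_fc = ifelse(excluded, NA_real_, log2(fc)),
    p_value = ifelse(excluded, NA_real_, p),
    degenerate = degenerate,
    excluded = excluded
  )
  dplyr::mutate(
    out,
    neg_log10_p = -log10(.data$p_value),
    selected = !.data$excluded &
      (.data$fc >= fc_threshold | .data$fc <= 1 / fc_threshold) &
      .data$p_value < p_threshold,
    .after = "p_value"
  )
}

.impute_half_min <- function(m) {
  if (!anyNA(m)) return(m)
  for (i in which(rowSums(is.na(m)) > 0)) {
    v <- m[i, ]
    pos <- v[!is.na(v) & v > 0]
    fill <- if (length(pos) > 0) min(pos) / 2 else 0
    m[i, is.na(v)] <- fill
  }
  m
}

#' Volcano plot
#'
#' @param volcano Output of [volcano_select()].
#' @param fc_threshold,p_threshold Thresholds to draw as guide lines
#'   (defaults 2 and 0.05, matching [volcano_select()] defaults).
#' @return A ggplot of log2 fold change against -log10 p, selected features
#'   in red.
#' @export
plot_volcano <- function(volcano, fc_threshold = 2, p_threshold = 0.05) {
  dat <- dplyr::filter(volcano, !.data$excluded)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2_fc,
                                    y = .data$neg_log10_p,
                                    colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(fc_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change (late / early)",
                  y = "-log10 p (paired t-test)") +
    ggplot2::theme_minimal()
}
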