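#' Simulation configuration for a paired LC-MS metabolomics study
#'
#' Describes the study design emulated by [simulate_study()]: a paired
#' two-timepoint serum acquisition on `n_subjects` animals, acquired in
#' positive and negative electrospray mode, with leading column-conditioning
#' QC injections, a pooled QC re-injected periodically through the sequence,
#' one internal-standard channel per mode, log-normal feature intensities
#' with a per-subject random effect, and a planted set of discriminant
#' features with known log2 fold changes.
#'
#' Defaults mirror the emulated study: 6 subjects, 4045 positive-mode and
#' 9712 negative-mode features, at least 5 conditioning QCs and a pooled QC
#' every 6 samples. Per-feature analytical CVs are log-normal with median
#' `cv_median` and `sdlog = log(3)/qnorm(1 - cv_tail_fraction)` so that a
#' fraction `cv_tail_fraction` of features exceed 3x the median CV
#' (with the defaults: median 10%, 15% of features at CV >= 30%),
#' exercising the QC filter.
#'
#' @param n_subjects Number of paired subjects (>= 3; default 6).
#' @param n_features_pos,n_features_neg Features per ionization mode
#'   (defaults 4045 and 9712).
#' @param fraction_discriminant Fraction of features per mode planted with a
#'   timepoint effect (default 0.01).
#' @param log2fc_range Range of planted |log2 fold change|, drawn uniformly
#'   (default `c(1, 3)`); the sign of each effect is random and recorded.
#' @param subject_sd Between-subject SD on the log10 scale (default 0.15).
#' @param cv_median Median per-feature analytical CV (default 0.10).
#' @param cv_tail_fraction Fraction of features with CV at least 3x the
#'   median (default 0.15).
#' @param cv_values Optional explicit per-feature CVs (recycled per mode),
#'   overriding the log-normal draw.
#' @param istd_drift Linear drift of the internal-standard area per
#'   injection, in area units (default 0).
#' @param istd_cv Analytical CV of the internal-standard channel (default
#'   0.02).
#' @param qc_pool_every Pooled-QC cadence: one QCpool after this many
#'   biological injections (default 6).
#' @param n_qc_cond Leading conditioning QC injections (default 5).
#' @param t_early,t_late Timepoint labels (defaults "T0", "T28").
#' @param baseline_log10_range Range of per-feature baseline abundance on
#'   the log10 scale (default `c(4, 7)`).
#' @param seed Integer RNG seed; a fixed seed makes the output
#'   bit-reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 6,
                       n_features_pos = 4045,
                       n_features_neg = 9712,
                       fraction_discriminant = 0.01,
                       log2fc_range = c(1, 3),
                       subject_sd = 0.15,
                       cv_median = 0.10,
                       cv_tail_fraction = 0.15,
                       cv_values = NULL,
                       istd_drift = 0,
                       istd_cv = 0.02,
                       qc_pool_every = 6,
                       n_qc_cond = 5,
                       t_early = "T0",
                       t_late = "T28",
                       baseline_log10_range = c(4, 7),
                       seed = 1) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_features_pos = as.integer(n_features_pos),
    n_features_neg = as.integer(n_features_neg),
    fraction_discriminant = fraction_discriminant,
    log2fc_range = log2fc_range,
    subject_sd = subject_sd,
    cv_median = cv_median,
    cv_tail_fraction = cv_tail_fraction,
    cv_values = cv_values,
    istd_drift = istd_drift,
    istd_cv = istd_cv,
    qc_pool_every = as.integer(qc_pool_every),
    n_qc_cond = as.integer(n_qc_cond),
    t_early = t_early,
    t_late = t_late,
    baseline_log10_range = baseline_log10_range,
    seed = as.integer(seed)
  )
  if (cfg$n_subjects < 3) abort("n_subjects must be >= 3.")
  for (f in c("fraction_discriminant", "cv_tail_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(paste0(f, " must be in [0, 1]."))
  }
  if (cfg$n_features_pos < 2 || cfg$n_features_neg < 2) {
    abort("Each mode needs at least 2 features.")
  }
  if (cfg$qc_pool_every < 1) abort("qc_pool_every must be >= 1.")
  if (cfg$cv_median <= 0) abort("cv_median must be positive.")
  structure(cfg, class = "sim_config")
}

#' Simulate a paired two-timepoint LC-MS study with known ground truth
#'
#' Generates positive- and negative-mode feature tables, the shared sample
#' sheet, and a ground-truth table. Baseline log10 abundance per feature is
#' uniform over `baseline_log10_range`; each subject carries a normal random
#' effect (SD `subject_sd`) shared across its two timepoints; discriminant
#' features receive `sign * log2FC * log10(2)` at the late timepoint;
#' analytical noise is log-normal at each feature's CV. Pooled-QC injections
#' are the per-feature mean of all biological samples plus fresh analytical
#' noise; conditioning QCs are copies of the first pooled-QC draw (they are
#' excluded from statistics downstream). One internal-standard channel per
#' mode has constant true area `1e5` plus `istd_drift` times the injection
#' order.
#'
#' @param config A [sim_config()].
#' @return A list with elements `pos` and `neg` (feature tables), `samples`
#'   (sample sheet), `truth` (tibble: `feature_id`, `mode`,
#'   `is_discriminant`, `log2_fc`, `true_cv`, `is_istd`) and `istd` (named
#'   character vector of internal-standard feature ids per mode).
#' @export
simulate_study <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)

  n_bio <- 2L * config$n_subjects
  subjects <- sprintf("R%02d", seq_len(config$n_subjects))

  # injection sequence: conditioning QCs, then bio blocks with pooled QCs
  bio_ids <- c(paste0(subjects, "_", config$t_early),
               paste0(subjects, "_", config$t_late))
  bio_order <- sample(bio_ids)
  seq_roles <- c(rep("qc_cond", config$n_qc_cond), "qc_pool")
  seq_ids <- c(sprintf("QCcond_%d", seq_len(config$n_qc_cond)), "QCpool_1")
  n_pool <- 1L
  for (i in seq_along(bio_order)) {
    seq_roles <- c(seq_roles, "biological")
    seq_ids <- c(seq_ids, bio_order[i])
    if (i %% config$qc_pool_every == 0 || i == length(bio_order)) {
      n_pool <- n_pool + 1L
      seq_roles <- c(seq_roles, "qc_pool")
      seq_ids <- c(seq_ids, sprintf("QCpool_%d", n_pool))
    }
  }
  bio_subject <- ifelse(seq_roles == "biological",
                        sub("_[^_]+$", "", seq_ids), NA_character_)
  bio_tp <- ifelse(seq_roles == "biological",
                   sub("^[^_]+_", "", seq_ids), NA_character_)
  samples <- tibble::tibble(
    sample_id = seq_ids,
    role = seq_roles,
    subject = bio_subject,
    timepoint = bio_tp,
    injection_order = seq_along(seq_ids)
  )
  validate_sample_sheet(samples)

  sim_mode <- function(mode, n_f) {
    mz <- runif(n_f, 100, 1700)
    rt <- runif(n_f, 0.3, 12)
    id <- sprintf("%.7f;%.3f", mz, rt)
    while (anyDuplicated(id)) {
      d <- duplicated(id)
      mz[d] <- mz[d] + runif(sum(d), 1e-4, 1e-3)
      id <- sprintf("%.7f;%.3f", mz, rt)
    }
    # the last feature row is the internal-standard channel
    n_all <- n_f
    istd_mz <- if (mode == "pos") 556.2766 else 607.2656
    mz[n_all] <- istd_mz
    rt[n_all] <- 2.5
    istd_id <- sprintf("%.7f;%.3f", istd_mz, 2.5)
    id[n_all] <- istd_id

    mu <- runif(n_all, config$baseline_log10_range[1],
                config$baseline_log10_range[2])
    mu[n_all] <- 5
    cv <- if (!is.null(config$cv_values)) {
      rep_len(config$cv_values, n_all)
    } else {
      rlnorm(n_all, meanlog = log(config$cv_median),
             sdlog = log(3) / qnorm(1 - config$cv_tail_fraction))
    }
    cv[n_all] <- config$istd_cv
    sd_log10 <- sqrt(log(1 + cv^2)) / log(10)

    n_disc <- round(config$fraction_discriminant * n_f)
    disc_idx <- if (n_disc > 0) sample.int(n_f - 1L, n_disc) else integer(0)
    log2_fc <- numeric(n_all)
    log2_fc[disc_idx] <- sample(c(-1, 1), n_disc, replace = TRUE) *
      runif(n_disc, config$log2fc_range[1], config$log2fc_range[2])

    subj_eff <- matrix(rnorm(n_all * config$n_subjects, 0, config$subject_sd),
                       n_all, config$n_subjects,
                       dimnames = list(NULL, subjects))

    bio_cols <- samples$sample_id[samples$role == "biological"]
    bio_subj <- samples$subject[samples$role == "biological"]
    bio_late <- samples$timepoint[samples$role == "biological"] ==
      config$t_late
    L <- mu + subj_eff[, bio_subj, drop = FALSE] +
      outer(log2_fc * log10(2), as.numeric(bio_late)) +
      matrix(rnorm(n_all * n_bio, 0, sd_log10), n_all, n_bio)
    bio_mat <- 10^L
    colnames(bio_mat) <- bio_cols

    pool_log10 <- log10(rowMeans(bio_mat))
    pool_cols <- samples$sample_id[samples$role == "qc_pool"]
    qc_mat <- 10^(pool_log10 +
                    matrix(rnorm(n_all * length(pool_cols), 0, sd_log10),
                           n_all, length(pool_cols)))
    colnames(qc_mat) <- pool_cols

    cond_cols <- samples$sample_id[samples$role == "qc_cond"]
    cond_mat <- matrix(qc_mat[, 1], n_all, length(cond_cols),
                       dimnames = list(NULL, cond_cols))

    full <- cbind(bio_mat, qc_mat, cond_mat)[, samples$sample_id,
                                             drop = FALSE]
    # internal standard: spiked per injection, drift in injection order
    istd_area <- (1e5 + config$istd_drift * samples$injection_order) *
      exp(rnorm(nrow(samples), 0, sqrt(log(1 + config$istd_cv^2))))
    full[n_all, ] <- istd_area

    tab <- tibble::tibble(feature_id = id, mz = mz, rt = rt, mode = mode)
    tab <- dplyr::bind_cols(tab, tibble::as_tibble(full))
    truth <- tibble::tibble(
      feature_id = id, mode = mode,
      is_discriminant = seq_len(n_all) %in% disc_idx,
      log2_fc = log2_fc,
      true_cv = cv,
      is_istd = id == istd_id
    )
    list(table = validate_feature_table(tab), truth = truth, istd = istd_id)
  }

  pos <- sim_mode("pos", config$n_features_pos)
  neg <- sim_mode("neg", config$n_features_neg)
  list(
    pos = pos$table,
    neg = neg$table,
    samples = samples,
    truth = dplyr::bind_rows(pos$truth, neg$truth),
    istd = c(pos = pos$istd, neg = neg$istd)
  )
}

#' Write all artifacts of a simulated study to a directory
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_feature_table(study$pos, file.path(dir, "features_pos.tsv"))
  write_feature_table(study$neg, file.path(dir, "features_neg.tsv"))
  write_sample_sheet(study$samples, file.path(dir, "samples.tsv"))
  .write_tsv_commented(study$truth, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
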