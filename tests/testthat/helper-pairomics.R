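# shared fixtures, all built in code

# strong-signal small preset: clearly separable planted effects, low noise
small_strong_config <- function(seed = 42) {
  sim_config(n_features_pos = 200, n_features_neg = 300,
             fraction_discriminant = 0.05, log2fc_range = c(2.5, 3),
             cv_median = 0.05, seed = seed)
}

# 3-feature x 4-sample handwritten table
tiny_feature_table <- function(mode = "pos") {
  tibble::tibble(
    feature_id = c("100.1;1.0", "200.2;2.0", "300.3;3.0"),
    mz = c(100.1, 200.2, 300.3),
    rt = c(1, 2, 3),
    mode = mode,
    S1 = c(10, 20, 30), S2 = c(11, 21, 31),
    S3 = c(12, 22, 32), S4 = c(13.5, NA, 33)
  )
}

# biological-only paired sheet: samples <subject>_<tp>
bio_sheet <- function(n_subjects = 6, tpts = c("T0", "T28")) {
  subj <- sprintf("R%02d", seq_len(n_subjects))
  grid <- expand.grid(subject = subj, timepoint = tpts,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    sample_id = paste0(grid$subject, "_", grid$timepoint),
    role = "biological",
    subject = grid$subject,
    timepoint = grid$timepoint,
    injection_order = seq_len(nrow(grid))
  )
}

# sheet of n_qc pooled QCs (plus two biological so pairing code has data)
qc_sheet <- function(n_qc = 3) {
  tibble::tibble(
    sample_id = sprintf("QCpool_%d", seq_len(n_qc)),
    role = "qc_pool",
    subject = NA_character_,
    timepoint = NA_character_,
    injection_order = seq_len(n_qc)
  )
}

# feature table with given per-feature QC intensity rows
qc_table <- function(rows, mode = "pos") {
  n_qc <- length(rows[[1]])
  tab <- tibble::tibble(
    feature_id = names(rows),
    mz = seq_along(rows) + 100,
    rt = seq_along(rows),
    mode = mode
  )
  m <- do.call(rbind, rows)
  colnames(m) <- sprintf("QCpool_%d", seq_len(n_qc))
  dplyr::bind_cols(tab, tibble::as_tibble(m))
}

# balanced two-class toy matrix with a separating first variable
separable_xy <- function(n = 20, p = 10, delta = 5, seed = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("V", seq_len(p))))
  y <- rep(c(-1, 1), each = n / 2)
  X[, 1] <- X[, 1] + delta / 2 * y
  list(x = X, y = y)
}

null_xy <- function(n = 20, p = 50, seed = 1) {
  set.seed(seed)
  list(x = matrix(rnorm(n * p), n, p,
                  dimnames = list(NULL, paste0("V", seq_len(p)))),
       y = rep(c(-1, 1), each = n / 2))
}
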