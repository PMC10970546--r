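test_that("the generator reproduces the study design and is deterministic", {
  cfg <- sim_config(n_features_pos = 50, n_features_neg = 80, seed = 11)
  st <- simulate_study(cfg)
  expect_equal(nrow(st$pos), 50)
  expect_equal(nrow(st$neg), 80)
  expect_equal(sum(st$samples$role == "biological"), 12)
  expect_equal(sum(st$samples$role == "qc_cond"), 5)
  # a pooled QC leads the run and one closes it
  expect_gte(sum(st$samples$role == "qc_pool"), 3)
  expect_silent(validate_sample_sheet(st$samples))
  expect_silent(validate_feature_table(st$pos))
  expect_equal(nrow(sample_pairs(st$samples, "T0", "T28")), 6)

  # planted set size and ground-truth bookkeeping
  expect_equal(sum(st$truth$is_discriminant[st$truth$mode == "pos"]),
               round(0.01 * 50))
  expect_true(all(st$truth$feature_id[st$truth$is_istd] == st$istd))
  expect_true(all(st$truth$log2_fc[!st$truth$is_discriminant] == 0))

  expect_identical(simulate_study(cfg), st)
  expect_false(identical(simulate_study(sim_config(n_features_pos = 50,
                                                   n_features_neg = 80,
                                                   seed = 12)),
                         st))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_subjects = 2), "n_subjects")
  expect_error(sim_config(fraction_discriminant = 1.2), "0, 1")
  expect_error(sim_config(qc_pool_every = 0), "qc_pool_every")
})

test_that("QC-pool replicate CV converges to the configured per-feature CV", {
  # ~20 pooled QCs per run, averaged over seeds
  devs <- purrr::map(1:5, function(s) {
    cfg <- sim_config(n_subjects = 9, n_features_pos = 100,
                      n_features_neg = 2, qc_pool_every = 1, seed = 300 + s)
    st <- simulate_study(cfg)
    qc <- intensity_matrix(
      st$pos, st$samples$sample_id[st$samples$role == "qc_pool"])
    emp <- apply(qc, 1, sd) / rowMeans(qc)
    truth <- st$truth[st$truth$mode == "pos", ]
    (emp - truth$true_cv)[truth$true_cv <= 0.4]
  })
  mean_abs_dev <- mean(abs(unlist(devs)))
  expect_lt(mean_abs_dev, 0.03)
})

test_that("planted fold changes are recovered as analytical noise vanishes", {
  cfg <- sim_config(n_features_pos = 60, n_features_neg = 2,
                    fraction_discriminant = 0.2, cv_values = 1e-4,
                    istd_cv = 1e-4, seed = 21)
  st <- simulate_study(cfg)
  pairs <- sample_pairs(st$samples, "T0", "T28")
  early <- intensity_matrix(st$pos, pairs$sample_early)
  late <- intensity_matrix(st$pos, pairs$sample_late)
  emp_log2fc <- rowMeans(log2(late / early))
  truth <- st$truth[st$truth$mode == "pos", ]
  expect_equal(emp_log2fc, truth$log2_fc, tolerance = 1e-2,
               ignore_attr = TRUE)
})

test_that("strong planted effects all clear the volcano thresholds", {
  cfg <- sim_config(n_features_pos = 150, n_features_neg = 2,
                    fraction_discriminant = 0.1, log2fc_range = c(3, 3),
                    cv_values = 0.05, seed = 8)
  st <- simulate_study(cfg)
  v <- volcano_select(st$pos, st$samples, "T0", "T28")
  truth <- st$truth[st$truth$mode == "pos", ]
  planted <- truth$feature_id[truth$is_discriminant]
  expect_true(all(planted %in% v$feature_id[v$selected]))
})

test_that("with no planted effects the volcano behaves like a null test", {
  # ~5% of features reach p < 0.05 by chance; almost none also pass FC >= 2
  frac_p <- purrr::map_dbl(1:5, function(s) {
    st <- simulate_study(sim_config(n_features_pos = 1000,
                                    n_features_neg = 1000,
                                    fraction_discriminant = 0, seed = 400 + s))
    v <- volcano_select(dplyr::bind_rows(st$pos, st$neg), st$samples,
                        "T0", "T28")
    mean(v$p_value < 0.05, na.rm = TRUE)
  })
  expect_gte(mean(frac_p), 0.03)
  expect_lte(mean(frac_p), 0.07)
})

test_that("a simulated study writes and reloads losslessly", {
  st <- simulate_study(sim_config(n_features_pos = 10, n_features_neg = 12,
                                  seed = 2))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_identical(read_feature_table(file.path(dir, "features_pos.tsv"),
                                      "pos"), st$pos)
  expect_identical(read_sample_sheet(file.path(dir, "samples.tsv")),
                   st$samples)
})
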