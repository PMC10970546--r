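test_that("ISTD report recovers flat and linear response patterns", {
  sheet <- qc_sheet(10)
  tab <- qc_table(list(istd = rep(1000, 10), other = 1:10 * 100))
  rep_flat <- istd_report(tab, sheet, "istd")
  expect_equal(rep_flat$slope, 0)
  expect_equal(rep_flat$cv_percent, 0)

  tab2 <- qc_table(list(istd = 1000 + 5 * (1:10)))
  rep_lin <- istd_report(tab2, sheet, "istd")
  expect_equal(rep_lin$slope, 5, tolerance = 1e-10)

  expect_error(istd_report(tab, sheet, "nope"), "not found")
  expect_error(istd_report(tab[, 1:6], qc_sheet(2), "istd"), "3 injections")
})

test_that("ISTD drift planted by the generator is recovered by least squares", {
  cfg <- sim_config(n_features_pos = 20, n_features_neg = 2,
                    istd_drift = 5, istd_cv = 0.005, seed = 31)
  st <- simulate_study(cfg)
  rep <- istd_report(st$pos, st$samples, st$istd[["pos"]])
  # planted slope lies inside the least-squares confidence interval
  half <- qt(0.975, df = nrow(rep$areas) - 2) * rep$slope_se
  expect_lt(abs(rep$slope - 5), half)

  # a drift large relative to the channel noise is detected
  st2 <- simulate_study(sim_config(n_features_pos = 20, n_features_neg = 2,
                                   istd_drift = 50, istd_cv = 0.005,
                                   seed = 31))
  rep_big <- istd_report(st2$pos, st2$samples, st2$istd[["pos"]])
  expect_lt(rep_big$slope_p, 0.05)
  expect_lt(abs(rep_big$slope - 50) / 50, 0.5)

  # normalization flattens the drift
  norm <- normalize_istd(st2$pos, st2$samples, st2$istd[["pos"]])
  rep2 <- istd_report(norm, st2$samples, st2$istd[["pos"]])
  expect_lt(abs(rep2$slope), 1e-8)
})

test_that("ISTD normalization scales samples to the median ISTD response", {
  sheet <- qc_sheet(5)
  tab <- qc_table(list(istd = c(100, 100, 200, 100, 100),
                       f1 = c(10, 20, 30, 40, 50)))
  norm <- normalize_istd(tab, sheet, "istd")
  # sample 3 had ISTD at 2x the median -> intensities halved
  expect_equal(norm$QCpool_3, c(100, 15))
  expect_equal(norm$QCpool_1, c(100, 10))

  # all-equal ISTD leaves the table unchanged
  tab2 <- qc_table(list(istd = rep(100, 5), f1 = c(10, 20, 30, 40, 50)))
  expect_equal(normalize_istd(tab2, sheet, "istd"), tab2)

  # idempotency
  expect_equal(normalize_istd(norm, sheet, "istd"), norm)

  tab3 <- qc_table(list(istd = c(100, 0, 100, 100, 100), f1 = rep(1, 5)))
  expect_error(normalize_istd(tab3, sheet, "istd"), "QCpool_2")
})

test_that("the QC CV filter implements the >= threshold contract", {
  sheet <- qc_sheet(3)
  tab <- qc_table(list(
    steady = c(100, 100, 100),   # CV 0
    wobbly = c(100, 150, 200),   # CV = 100*50/150 = 33.3 -> removed
    border = c(70, 100, 130)     # sd/mean = 0.30 exactly
  ))
  expect_equal(sd(c(70, 100, 130)) / mean(c(70, 100, 130)), 0.3,
               tolerance = 1e-12)

  res <- qc_cv_filter(tab, sheet, threshold_percent = 30)
  expect_true(res$retained[res$feature_id == "steady"])
  expect_false(res$retained[res$feature_id == "wobbly"])
  expect_equal(res$qc_cv_percent[res$feature_id == "wobbly"], 100 * 50 / 150)
  # comparison is >=, so exactly 30% is removed
  expect_false(res$retained[res$feature_id == "border"])

  expect_error(qc_cv_filter(tab[, 1:6], qc_sheet(2)), "3 qc_pool")
})

test_that("features unquantifiable in QC are removed as missing", {
  sheet <- qc_sheet(4)
  tab <- qc_table(list(
    ghost = c(NA, NA, NA, 100),   # observed in 1/4 -> removed
    patchy = c(100, NA, 105, 95)  # observed in 3/4 -> CV on observed
  ))
  res <- qc_cv_filter(tab, sheet)
  expect_false(res$retained[res$feature_id == "ghost"])
  expect_equal(res$reason[res$feature_id == "ghost"], "missing")
  expect_true(res$retained[res$feature_id == "patchy"])
  expect_equal(res$qc_cv_percent[res$feature_id == "patchy"],
               100 * sd(c(100, 105, 95)) / mean(c(100, 105, 95)))
})

test_that("the CV filter partitions features and ignores column order and scale", {
  st <- simulate_study(sim_config(n_features_pos = 100, n_features_neg = 2,
                                  n_subjects = 9, qc_pool_every = 2,
                                  seed = 17))
  res <- qc_cv_filter(st$pos, st$samples)
  expect_equal(sum(res$retained) + sum(!res$retained), nrow(st$pos))
  expect_setequal(res$feature_id, st$pos$feature_id)

  # shuffle sample columns
  sc <- sample_columns(st$pos)
  meta <- c("feature_id", "mz", "rt", "mode")
  shuffled <- dplyr::select(st$pos, dplyr::all_of(c(meta, rev(sc))))
  res2 <- qc_cv_filter(shuffled, st$samples)
  expect_equal(res2$retained[match(res$feature_id, res2$feature_id)],
               res$retained)

  # global rescaling does not change CV decisions
  scaled <- st$pos
  for (s in sc) scaled[[s]] <- scaled[[s]] * 1e3
  res3 <- qc_cv_filter(scaled, st$samples)
  expect_equal(res3$retained, res$retained)
})
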