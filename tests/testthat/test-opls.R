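test_that("with no orthogonal components the model reduces to PLS1-DA", {
  d <- separable_xy()
  m <- fit_oplsda(d$x, d$y, n_ortho = 0)
  ours <- predict(m, d$x)$y_hat

  # independent single-component PLS1 on autoscaled data
  Xs <- scale(d$x)
  yc <- d$y - mean(d$y)
  w <- crossprod(Xs, yc)
  w <- w / sqrt(sum(w^2))
  t1 <- Xs %*% w
  oracle <- as.numeric(t1 * sum(yc * t1) / sum(t1^2) + mean(d$y))
  expect_lt(max(abs(ours - oracle)), 1e-10)
})

test_that("predictions with n_ortho = 0 match mixOmics one-component PLS", {
  skip_if_not_installed("mixOmics")
  d <- separable_xy()
  m <- fit_oplsda(d$x, d$y, n_ortho = 0)
  ours <- predict(m, d$x)$y_hat
  mo <- mixOmics::pls(d$x, d$y, ncomp = 1, scale = TRUE, mode = "regression")
  theirs <- predict(mo, d$x)$predict[, 1, 1]
  expect_lt(max(abs(ours - theirs)), 1e-10)
})

test_that("well-separated classes give a near-perfect training fit", {
  d <- separable_xy(n = 20, p = 10, delta = 5)
  m <- fit_oplsda(d$x, d$y, n_ortho = "auto")
  expect_gt(m$r2y, 0.85)
  # every training prediction has the correct sign
  expect_true(all(sign(predict(m, d$x)$y_hat) == sign(d$y)))
})

test_that("orthogonal scores are orthogonal to the class vector", {
  for (s in 1:5) {
    st <- null_xy(seed = 40 + s)
    m <- fit_oplsda(st$x, st$y, n_ortho = 2)
    for (k in seq_len(ncol(m$t_o))) {
      expect_lt(abs(cor(m$t_o[, k], m$y)), 1e-8)
    }
    expect_equal(sum(m$w^2), 1, tolerance = 1e-12)
  }
})

test_that("column permutation permutes weights and preserves scores", {
  d <- separable_xy()
  m1 <- fit_oplsda(d$x, d$y, n_ortho = 1)
  perm <- c(3, 1, 2, 7, 10, 4, 5, 9, 8, 6)
  m2 <- fit_oplsda(d$x[, perm], d$y, n_ortho = 1)
  expect_equal(m2$t, m1$t, tolerance = 1e-10)
  expect_equal(m2$w[colnames(d$x)], m1$w, tolerance = 1e-10)
})

test_that("model fitting rejects degenerate inputs", {
  d <- separable_xy()
  expect_error(fit_oplsda(d$x, rep(1, 20)), "two")
  expect_error(fit_oplsda(cbind(d$x, const = 1), d$y), "Zero-variance")
  expect_error(fit_oplsda(d$x, d$y, n_ortho = 50), "rank")
  x_na <- d$x; x_na[1, 1] <- NA
  expect_error(fit_oplsda(x_na, d$y), "missing")
})

test_that("Q2 approaches 1 for a noiseless predictor", {
  sig <- rep(c(-1, 1), each = 10)
  X <- cbind(sig = sig, sig2 = 2 * sig)
  cv <- oplsda_cv(X, sig, n_ortho = 0, folds = 7, seed = 1)
  expect_gt(cv$q2, 0.99)
})

test_that("cross-validation matches a no-leakage oracle and detects leakage", {
  st <- simulate_study(small_strong_config(2))
  v <- volcano_select(dplyr::bind_rows(st$pos, st$neg), st$samples,
                      "T0", "T28")
  pairs <- sample_pairs(st$samples, "T0", "T28")
  sel <- dplyr::filter(v, selected)
  tab <- dplyr::bind_rows(st$pos, st$neg)
  tab <- tab[match(paste(sel$mode, sel$feature_id),
                   paste(tab$mode, tab$feature_id)), ]
  X <- t(log10(intensity_matrix(tab, c(pairs$sample_early,
                                       pairs$sample_late))))
  colnames(X) <- paste0(tab$mode, ":", tab$feature_id)
  y <- rep(c(-1, 1), each = nrow(pairs))

  cv <- oplsda_cv(X, y, n_ortho = 1, folds = 4, seed = 3)

  # independent oracle: explicit loops, scale() and fresh O-PLS algebra,
  # re-estimating everything inside each training fold
  press <- 0
  for (k in sort(unique(cv$fold_of))) {
    tr <- cv$fold_of != k
    Xtr <- scale(X[tr, , drop = FALSE])
    ctr <- attr(Xtr, "scaled:center"); str_ <- attr(Xtr, "scaled:scale")
    ytr <- y[tr] - mean(y[tr])
    w <- crossprod(Xtr, ytr); w <- w / sqrt(sum(w^2))
    t1 <- Xtr %*% w
    p1 <- crossprod(Xtr, t1) / sum(t1^2)
    wo <- p1 - as.numeric(crossprod(w, p1)) * w
    wo <- wo / sqrt(sum(wo^2))
    to <- Xtr %*% wo
    po <- crossprod(Xtr, to) / sum(to^2)
    Xd <- Xtr - to %*% t(po)
    w2 <- crossprod(Xd, ytr); w2 <- w2 / sqrt(sum(w2^2))
    t2 <- Xd %*% w2
    cy <- sum(ytr * t2) / sum(t2^2)
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, ctr), 2, str_, "/")
    Xte <- Xte - (Xte %*% wo) %*% t(po)
    yhat <- as.numeric(Xte %*% w2) * cy + mean(y[tr])
    press <- press + sum((y[!tr] - yhat)^2)
  }
  q2_oracle <- 1 - press / sum((y - mean(y))^2)
  expect_equal(cv$q2, q2_oracle, tolerance = 1e-12)

  # leaky variant (scaling estimated on all samples) must differ
  Xall <- scale(X)
  press_leak <- 0
  for (k in sort(unique(cv$fold_of))) {
    tr <- cv$fold_of != k
    ytr <- y[tr] - mean(y[tr])
    Xtr <- Xall[tr, , drop = FALSE]
    w <- crossprod(Xtr, ytr); w <- w / sqrt(sum(w^2))
    t1 <- Xtr %*% w
    p1 <- crossprod(Xtr, t1) / sum(t1^2)
    wo <- p1 - as.numeric(crossprod(w, p1)) * w
    wo <- wo / sqrt(sum(wo^2))
    to <- Xtr %*% wo
    po <- crossprod(Xtr, to) / sum(to^2)
    Xd <- Xtr - to %*% t(po)
    w2 <- crossprod(Xd, ytr); w2 <- w2 / sqrt(sum(w2^2))
    t2 <- Xd %*% w2
    cy <- sum(ytr * t2) / sum(t2^2)
    Xte <- Xall[!tr, , drop = FALSE]
    Xte <- Xte - (Xte %*% wo) %*% t(po)
    yhat <- as.numeric(Xte %*% w2) * cy + mean(y[tr])
    press_leak <- press_leak + sum((y[!tr] - yhat)^2)
  }
  q2_leak <- 1 - press_leak / sum((y - mean(y))^2)
  expect_false(isTRUE(all.equal(cv$q2, q2_leak, tolerance = 1e-12)))
})

test_that("Q2 is reproducible given the seed and fold assignment", {
  d <- null_xy(seed = 77)
  cv1 <- oplsda_cv(d$x, d$y, n_ortho = 1, seed = 5)
  cv2 <- oplsda_cv(d$x, d$y, n_ortho = 1, seed = 5)
  expect_identical(cv1$q2, cv2$q2)

  # same folds under a sample reordering give the same Q2
  ord <- sample(seq_along(d$y))
  cv3 <- oplsda_cv(d$x[ord, ], d$y[ord], n_ortho = 1,
                   fold_of = cv1$fold_of[ord])
  expect_equal(cv3$q2, cv1$q2, tolerance = 1e-12)
})

test_that("CV-ANOVA follows its closed form and limits", {
  fake_cv <- function(press, ss_tot, n, a) {
    structure(list(press = press, ss_tot = ss_tot, n = n,
                   n_components = a), class = "oplsda_cv")
  }
  r <- cv_anova(fake_cv(10, 10, 20, 2))
  expect_equal(r$f_statistic, 0)
  expect_equal(r$p_value, 1)

  r2 <- cv_anova(fake_cv(1e-12, 10, 20, 2))
  expect_lt(r2$p_value, 1e-10)
  expect_equal(r2$df1, 2)
  expect_equal(r2$df2, 17)

  expect_error(cv_anova(fake_cv(1, 10, 3, 2)), "Too few")

  # strong synthetic signal is highly significant
  d <- separable_xy()
  cv <- oplsda_cv(d$x, d$y, n_ortho = 0, seed = 2)
  expect_lt(cv_anova(cv)$p_value, 0.01)
})

test_that("the permutation p-value uses the add-one estimator", {
  d <- separable_xy(n = 16, p = 8, delta = 6, seed = 10)
  perm <- oplsda_permutation(d$x, d$y, n_ortho = 0, n_iterations = 99,
                             seed = 4)
  expect_equal(nrow(perm$permuted), 99)
  # observed beats every permutation here
  expect_equal(perm$p_q2, 1 / 100)
  expect_gte(perm$p_q2, 1 / (99 + 1)) # can never be zero
  expect_true(all(perm$permuted$correlation >= 0))
  expect_warning(oplsda_permutation(d$x, d$y, 0, n_iterations = 5, seed = 1),
                 "resolution")

  # reproducible under the same seed
  perm2 <- oplsda_permutation(d$x, d$y, n_ortho = 0, n_iterations = 99,
                              seed = 4)
  expect_identical(perm$p_q2, perm2$p_q2)
  expect_identical(perm$permuted$q2y, perm2$permuted$q2y)
})

test_that("VIP scores follow the closed form and normalize to the variable count", {
  # engineered weights (1, 0): V2 exactly orthogonal to y
  y <- c(1, 1, -1, -1)
  X <- cbind(V1 = y * 2, V2 = c(1, -1, -1, 1))
  m <- fit_oplsda(X, y, n_ortho = 0)
  v <- vip_scores(m)
  expect_equal(v$vip[v$variable == "V1"], sqrt(2), tolerance = 1e-10)
  expect_equal(v$vip[v$variable == "V2"], 0, tolerance = 1e-10)

  # sum VIP^2 = p on arbitrary fits
  for (s in 1:3) {
    d <- null_xy(n = 12, p = 30, seed = 50 + s)
    m <- fit_oplsda(d$x, d$y, n_ortho = 1)
    v <- vip_scores(m)
    expect_equal(sum(v$vip^2), 30, tolerance = 1e-6)
    expect_setequal(v$rank, 1:30)
  }
})

test_that("variable selection needs both rank and a CI excluding zero", {
  vip <- tibble::tibble(
    variable = paste0("v", 1:5),
    vip = c(3, 2.5, 2, 1.5, 1),
    ci_lower = c(2.5, -0.2, 1.4, 0.9, 0.4),
    ci_upper = c(3.5, 3.1, 2.6, 2.1, 1.6),
    rank = 1:5
  )
  sel <- select_vip(vip, top_n = 30)
  # rank 2 has CI touching zero -> dropped; 4 of 5 remain
  expect_equal(sum(sel$selected), 4)
  expect_false(sel$selected[sel$variable == "v2"])

  sel2 <- select_vip(dplyr::mutate(vip, rank = c(1, 2, 31, 4, 5)), top_n = 30)
  expect_false(sel2$selected[sel2$variable == "v3"])
})

test_that("tidy, glance and plots expose the fit", {
  d <- separable_xy()
  m <- fit_oplsda(d$x, d$y, n_ortho = 1)
  td <- generics::tidy(m)
  expect_equal(nrow(td), 10)
  expect_named(td, c("variable", "weight", "loading", "vip"))
  gl <- generics::glance(m)
  expect_equal(gl$n_ortho, 1L)
  expect_s3_class(ggplot2::autoplot(m), "ggplot")
  expect_s3_class(plot_vip(select_vip(vip_scores(m))), "ggplot")
})
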