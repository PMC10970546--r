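# Orthogonal projections to latent structures for a binary class response
# (O-PLS, Trygg & Wold flavour): orthogonal components are stripped from X
# by iterating w_ortho = p - (w'p) w on the deflated matrix, then a single
# predictive component is fit on the filtered X.

#' Fit an OPLS-DA model
#'
#' Variables are autoscaled (mean 0, unit variance); the two-level class
#' vector is coded -1/+1 and centered. `n_ortho` orthogonal (class-
#' uncorrelated) components are removed from X before a single predictive
#' component is fit; with `n_ortho = 0` the model is exactly a
#' one-component PLS1-DA. `n_ortho = "auto"` adds orthogonal components
#' while cross-validated Q2Y improves by more than `q2_tol`, up to
#' `max_ortho`.
#'
#' @param x Samples-by-variables numeric matrix (or data frame). No missing
#'   values; zero-variance variables must be removed beforehand.
#' @param y Class labels: a factor/character/logical with exactly two
#'   levels, or a numeric vector in \{-1, 1\}. At least 2 samples per class.
#' @param n_ortho Number of orthogonal components, or `"auto"`.
#' @param folds,seed Cross-validation settings used when
#'   `n_ortho = "auto"` (see [oplsda_cv()]).
#' @param q2_tol Minimum Q2Y improvement to accept one more orthogonal
#'   component under `"auto"` (default 0.01).
#' @param max_ortho Cap on orthogonal components under `"auto"` (default 5).
#' @return An object of class `oplsda`: weights `w`, loadings `p`, scores
#'   `t`, y-loading `c_y`, orthogonal `w_o`/`p_o`/`t_o` matrices, `n_ortho`,
#'   `r2y`, the scaling parameters, and the training data.
#' @export
fit_oplsda <- function(x, y, n_ortho = "auto", folds = 7, seed = 1,
                       q2_tol = 0.01, max_ortho = 5) {
  x <- .as_X(x)
  yy <- .code_y(y)
  if (nrow(x) != length(yy$y)) abort("nrow(x) must equal length(y).")
  if (anyNA(x)) abort("x must not contain missing values.")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Zero-variance variable(s): ",
                 paste(head(colnames(x)[sds == 0], 5), collapse = ", "),
                 ". Remove them before fitting."))
  }

  if (identical(n_ortho, "auto")) {
    best <- 0L
    q2_best <- oplsda_cv(x, y, n_ortho = 0, folds = folds, seed = seed)$q2
    while (best < max_ortho) {
      q2_next <- oplsda_cv(x, y, n_ortho = best + 1L, folds = folds,
                           seed = seed)$q2
      if (q2_next > q2_best + q2_tol) {
        best <- best + 1L
        q2_best <- q2_next
      } else {
        break
      }
    }
    n_ortho <- best
    q2y <- q2_best
  } else {
    q2y <- NA_real_
  }
  n_ortho <- as.integer(n_ortho)

  center <- colMeans(x)
  Xs <- .scale_apply(x, center, sds)
  if (n_ortho >= qr(Xs)$rank) {
    abort("n_ortho must be smaller than the rank of the scaled data matrix.")
  }
  core <- .opls_core(Xs, yy$y - mean(yy$y), n_ortho)
  fitted <- core$t * core$c_y + mean(yy$y)
  ss_res <- sum((yy$y - fitted)^2)
  ss_tot <- sum((yy$y - mean(yy$y))^2)
  structure(list(
    w = core$w, p = core$p, t = core$t, c_y = core$c_y,
    w_o = core$w_o, p_o = core$p_o, t_o = core$t_o,
    n_ortho = n_ortho,
    r2y = 1 - ss_res / ss_tot,
    q2y = q2y,
    center = center, scale = sds,
    y = yy$y, y_levels = yy$levels, x = x,
    folds = folds, seed = seed
  ), class = "oplsda")
}

.as_X <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  x
}

.code_y <- function(y) {
  if (is.numeric(y)) {
    lev <- sort(unique(y))
    if (!all(y %in% c(-1, 1)) || length(lev) != 2) {
      abort("Numeric y must take exactly the two values -1 and 1.")
    }
    return(list(y = as.numeric(y), levels = c("-1", "1")))
  }
  f <- factor(y)
  if (nlevels(f) != 2) abort("y must have exactly two classes.")
  if (min(table(f)) < 2) abort("Need at least 2 samples per class.")
  list(y = ifelse(as.integer(f) == 1L, -1, 1), levels = levels(f))
}

.scale_apply <- function(x, center, scale) {
  out <- sweep(x, 2, center, "-")
  s <- ifelse(scale > 0, scale, Inf) # zero-variance (in a CV fold) -> 0
  sweep(out, 2, s, "/")
}

.opls_core <- function(Xs, yc, n_ortho) {
  p_vars <- ncol(Xs)
  W_o <- matrix(0, p_vars, 0)
  P_o <- matrix(0, p_vars, 0)
  T_o <- matrix(0, nrow(Xs), 0)
  Xf <- Xs
  for (k in seq_len(n_ortho)) {
    w <- crossprod(Xf, yc)
    w <- w / sqrt(sum(w^2))
    t <- Xf %*% w
    p <- crossprod(Xf, t) / sum(t^2)
    wo <- p - as.numeric(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break # no y-orthogonal variation left
    wo <- wo / nwo
    to <- Xf %*% wo
    po <- crossprod(Xf, to) / sum(to^2)
    Xf <- Xf - to %*% t(po)
    W_o <- cbind(W_o, wo)
    P_o <- cbind(P_o, po)
    T_o <- cbind(T_o, to)
  }
  w <- crossprod(Xf, yc)
  w <- w / sqrt(sum(w^2))
  t <- as.numeric(Xf %*% w)
  p <- as.numeric(crossprod(Xf, t) / sum(t^2))
  c_y <- sum(yc * t) / sum(t^2)
  list(w = setNames(as.numeric(w), colnames(Xs)),
       p = setNames(p, colnames(Xs)),
       t = t, c_y = c_y, w_o = W_o, p_o = P_o, t_o = T_o)
}

.opls_predict_score <- function(core, Xs) {
  Xf <- Xs
  for (k in seq_len(ncol(core$w_o))) {
    to <- Xf %*% core$w_o[, k]
    Xf <- Xf - to %*% t(core$p_o[, k])
  }
  as.numeric(Xf %*% core$w)
}

#' Predict from an OPLS-DA model
#'
#' @param object An [fit_oplsda()] model.
#' @param newdata Samples-by-variables matrix with the training variables.
#' @param ... Unused.
#' @return A tibble with `score` (predictive component score), `y_hat`
#'   (continuous prediction on the -1/+1 scale) and `class` (nearest
#'   level).
#' @export
predict.oplsda <- function(object, newdata, ...) {
  Xs <- .scale_apply(.as_X(newdata)[, names(object$w), drop = FALSE],
                     object$center, object$scale)
  score <- .opls_predict_score(object, Xs)
  y_hat <- score * object$c_y + mean(object$y)
  tibble::tibble(
    score = score,
    y_hat = y_hat,
    class = object$y_levels[ifelse(y_hat < 0, 1L, 2L)]
  )
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf("OPLS-DA: 1 predictive + %d orthogonal component(s), %d x %d\n",
              x$n_ortho, nrow(x$x), ncol(x$x)))
  cat(sprintf("  R2Y = %.3f", x$r2y))
  if (!is.na(x$q2y)) cat(sprintf(", Q2Y = %.3f (from auto selection)", x$q2y))
  cat("\n")
  invisible(x)
}

#' Cross-validated predictive ability (Q2Y)
#'
#' Stratified k-fold cross-validation of the OPLS-DA model:
#' `Q2Y = 1 - PRESS / SS_tot` with `PRESS = sum((y_i - yhat_i,cv)^2)` over
#' out-of-fold predictions and `SS_tot = sum((y_i - mean(y))^2)`. Scaling
#' parameters and all model components are re-estimated inside each
#' training fold, so no information leaks from held-out samples.
#'
#' @inheritParams fit_oplsda
#' @param n_ortho Number of orthogonal components (integer; the model
#'   settings are fixed before validation).
#' @param folds Number of folds (default 7). Fold assignment is stratified
#'   by class and seeded.
#' @param seed Integer seed for the fold assignment.
#' @param fold_of Optional explicit fold assignment (integer vector, one
#'   entry per sample), overriding `folds`/`seed`.
#' @return A list of class `oplsda_cv`: `q2`, `press`, `ss_tot`,
#'   `predictions` (tibble `sample`, `fold`, `y`, `y_hat`), `fold_of`
#'   (integer vector), `n_components` (predictive + orthogonal), `n`.
#' @export
oplsda_cv <- function(x, y, n_ortho, folds = 7, seed = 1, fold_of = NULL) {
  x <- .as_X(x)
  yy <- .code_y(y)
  n <- length(yy$y)
  n_ortho <- as.integer(n_ortho)

  fold_of <- fold_of %||% .make_folds(yy$y, folds, seed)
  y_hat <- numeric(n)
  for (k in sort(unique(fold_of))) {
    tr <- fold_of != k
    if (length(unique(yy$y[tr])) < 2) {
      abort("A training fold contained a single class; use fewer folds.")
    }
    center <- colMeans(x[tr, , drop = FALSE])
    scl <- apply(x[tr, , drop = FALSE], 2, sd)
    Xtr <- .scale_apply(x[tr, , drop = FALSE], center, scl)
    ybar <- mean(yy$y[tr])
    core <- .opls_core(Xtr, yy$y[tr] - ybar, n_ortho)
    Xte <- .scale_apply(x[!tr, , drop = FALSE], center, scl)
    y_hat[!tr] <- .opls_predict_score(core, Xte) * core$c_y + ybar
  }
  press <- sum((yy$y - y_hat)^2)
  ss_tot <- sum((yy$y - mean(yy$y))^2)
  structure(list(
    q2 = 1 - press / ss_tot,
    press = press,
    ss_tot = ss_tot,
    predictions = tibble::tibble(
      sample = rownames(x) %||% as.character(seq_len(n)),
      fold = fold_of, y = yy$y, y_hat = y_hat
    ),
    fold_of = fold_of,
    n_components = 1L + n_ortho,
    n = n
  ), class = "oplsda_cv")
}

# stratified, seeded fold assignment; retries (reseeding) if a training
# fold would be single-class, then errors
.make_folds <- function(y_num, folds, seed, max_attempts = 10) {
  n <- length(y_num)
  folds <- min(folds, n)
  for (attempt in seq_len(max_attempts)) {
    rng <- .local_rng(seed + (attempt - 1L) * 1000003L)
    fold_of <- integer(n)
    for (cls in unique(y_num)) {
      idx <- which(y_num == cls)
      idx <- idx[rng$sample(length(idx))]
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
    ok <- all(vapply(unique(fold_of), function(k) {
      length(unique(y_num[fold_of != k])) == 2
    }, logical(1)))
    if (ok) return(fold_of)
  }
  abort("Could not build folds with both classes in every training set.")
}

# seeded RNG that does not disturb the global stream
.local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  list(
    sample = function(n, size = n, replace = FALSE) {
      prev <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else {
        NULL
      }
      assign(".Random.seed", env$state, globalenv())
      out <- sample.int(n, size = size, replace = replace)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(prev)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", prev, globalenv())
      }
      out
    }
  )
}

#' CV-ANOVA model significance
#'
#' F-test comparing the cross-validated prediction residuals against the
#' total variation of the class variable:
#' `F = ((SS_tot - PRESS)/A) / (PRESS/(N - A - 1))` with `A` the total
#' number of fitted components (predictive + orthogonal) and `N` the sample
#' count. `SS_tot - PRESS` is floored at zero, so a model with no
#' cross-validated predictive ability gets `F = 0`, `p = 1`.
#'
#' @param cv An [oplsda_cv()] result.
#' @return A tibble with `f_statistic`, `df1`, `df2`, `p_value`.
#' @export
cv_anova <- function(cv) {
  d1 <- cv$n_components
  d2 <- cv$n - cv$n_components - 1L
  if (d2 <= 0) abort("Too few samples for CV-ANOVA (df2 <= 0).")
  explained <- max(cv$ss_tot - cv$press, 0)
  f <- (explained / d1) / (cv$press / d2)
  tibble::tibble(
    f_statistic = f, df1 = d1, df2 = d2,
    p_value = pf(f, d1, d2, lower.tail = FALSE)
  )
}

#' Permutation test of an OPLS-DA model
#'
#' Refits the model (with identical component count and cross-validation
#' settings) under `n_iterations` random permutations of the class labels,
#' building null distributions of R2Y and Q2Y. The permutation p-value uses
#' the add-one estimator `p = (1 + #\{Q2_perm >= Q2_obs\}) / (n + 1)`, so it
#' can never be zero. Regression intercepts of permuted R2/Q2 against the
#' absolute correlation of each permuted y with the original y (including
#' the observed point at correlation 1) summarise the familiar permutation
#' plot.
#'
#' @inheritParams oplsda_cv
#' @param n_iterations Number of permutations (default 1000; fewer than 20
#'   triggers a warning about p-value resolution).
#' @param seed Integer seed; mandatory for reproducibility (default 1).
#' @return A list of class `oplsda_permutation`: `observed` (tibble `r2y`,
#'   `q2y`), `permuted` (tibble `iteration`, `correlation`, `r2y`, `q2y`),
#'   `p_q2`, `r2_intercept`, `q2_intercept`, `n_iterations`.
#' @export
oplsda_permutation <- function(x, y, n_ortho, n_iterations = 1000, folds = 7,
                               seed = 1) {
  if (n_iterations < 20) {
    warn("Fewer than 20 permutations: p-value resolution is poor.")
  }
  x <- .as_X(x)
  yy <- .code_y(y)
  n_ortho <- as.integer(n_ortho)

  obs_fit <- fit_oplsda(x, y, n_ortho = n_ortho)
  obs_cv <- oplsda_cv(x, y, n_ortho = n_ortho, folds = folds, seed = seed)

  rng <- .local_rng(seed)
  res <- purrr::map(seq_len(n_iterations), function(i) {
    y_perm <- yy$y[rng$sample(length(yy$y))]
    fit <- fit_oplsda(x, y_perm, n_ortho = n_ortho)
    cv <- oplsda_cv(x, y_perm, n_ortho = n_ortho, folds = folds,
                    seed = seed + i)
    tibble::tibble(
      iteration = i,
      correlation = abs(stats::cor(y_perm, yy$y)),
      r2y = fit$r2y,
      q2y = cv$q2
    )
  })
  permuted <- dplyr::bind_rows(res)

  corr_all <- c(permuted$correlation, 1)
  r2_all <- c(permuted$r2y, obs_fit$r2y)
  q2_all <- c(permuted$q2y, obs_cv$q2)
  structure(list(
    observed = tibble::tibble(r2y = obs_fit$r2y, q2y = obs_cv$q2),
    permuted = permuted,
    p_q2 = (1 + sum(permuted$q2y >= obs_cv$q2)) / (n_iterations + 1),
    r2_intercept = unname(coef(lm(r2_all ~ corr_all))[1]),
    q2_intercept = unname(coef(lm(q2_all ~ corr_all))[1]),
    n_iterations = n_iterations
  ), class = "oplsda_permutation")
}

#' @export
print.oplsda_permutation <- function(x, ...) {
  cat(sprintf("Permutation test (%d iterations)\n", x$n_iterations))
  cat(sprintf("  observed R2Y = %.3f, Q2Y = %.3f\n",
              x$observed$r2y, x$observed$q2y))
  cat(sprintf("  p(Q2) = %.4g; intercepts R2 = %.3f, Q2 = %.3f\n",
              x$p_q2, x$r2_intercept, x$q2_intercept))
  invisible(x)
}

#' Permutation plot
#'
#' @param perm An [oplsda_permutation()] result.
#' @return A ggplot of permuted (and observed) R2Y/Q2Y against the absolute
#'   correlation of the permuted class vector with the original.
#' @export
plot_permutation <- function(perm) {
  dat <- dplyr::bind_rows(
    dplyr::mutate(
      tidyr::pivot_longer(perm$permuted, c("r2y", "q2y"),
                          names_to = "metric"),
      observed = FALSE),
    tibble::tibble(
      iteration = NA_integer_, correlation = 1,
      metric = c("r2y", "q2y"),
      value = c(perm$observed$r2y, perm$observed$q2y),
      observed = TRUE)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$correlation, y = .data$value,
                                    colour = .data$metric,
                                    shape = .data$observed)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = "|correlation with original y|", y = "R2Y / Q2Y") +
    ggplot2::theme_minimal()
}

#' VIP scores with jackknife confidence intervals
#'
#' Variable importance in projection on the predictive component:
#' `VIP_j = sqrt(p * w_j^2 / sum(w^2))`, which for the single predictive
#' component guarantees `sum(VIP^2) = p` (the variable count). Confidence
#' intervals come from a jackknife over the cross-validation training
#' subsets: the model is refit on each leave-one-fold-out subset and the
#' interval is `mean +/- t(0.975, K-1) * jackknife SE`.
#'
#' @param model A fitted [fit_oplsda()] model.
#' @param cv Optional matching [oplsda_cv()] result; its folds are reused.
#'   When absent, folds are built from `model$folds` and `model$seed`.
#' @return A tibble of class `vip_table`: `variable`, `vip`, `ci_lower`,
#'   `ci_upper`, `rank` (1 = most discriminant; ties broken by variable
#'   id).
#' @export
vip_scores <- function(model, cv = NULL) {
  p_vars <- length(model$w)
  vip <- sqrt(p_vars * model$w^2 / sum(model$w^2))

  fold_of <- if (!is.null(cv)) {
    cv$fold_of
  } else {
    .make_folds(model$y, model$folds, model$seed)
  }
  ks <- sort(unique(fold_of))
  K <- length(ks)
  vip_jack <- vapply(ks, function(k) {
    tr <- fold_of != k
    xs <- model$x[tr, , drop = FALSE]
    center <- colMeans(xs)
    scl <- apply(xs, 2, sd)
    core <- .opls_core(.scale_apply(xs, center, scl),
                       model$y[tr] - mean(model$y[tr]), model$n_ortho)
    sqrt(p_vars * core$w^2 / sum(core$w^2))
  }, numeric(p_vars))
  jack_mean <- rowMeans(vip_jack)
  jack_se <- sqrt((K - 1) / K *
                    rowSums((vip_jack - jack_mean)^2))
  half <- qt(0.975, df = K - 1) * jack_se

  out <- tibble::tibble(
    variable = names(model$w),
    vip = unname(vip),
    ci_lower = unname(jack_mean - half),
    ci_upper = unname(jack_mean + half)
  ) |>
    dplyr::arrange(dplyr::desc(.data$vip), .data$variable) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- c("vip_table", class(out))
  out
}

#' Select variables from a VIP table
#'
#' A variable is selected when it ranks within the first `top_n` by VIP
#' score and its jackknife confidence interval excludes zero (lower bound
#' strictly positive) — an unstable importance estimate, however large, is
#' discarded. When fewer than `top_n` variables exist, all are rank
#' candidates.
#'
#' @param vip A [vip_scores()] table.
#' @param top_n Rank cutoff (default 30).
#' @return The table with a `selected` logical column.
#' @export
select_vip <- function(vip, top_n = 30) {
  dplyr::mutate(vip,
                selected = .data$rank <= top_n & .data$ci_lower > 0)
}

#' VIP plot
#'
#' @param vip A [vip_scores()] (optionally [select_vip()]-flagged) table.
#' @param top_n Number of top-ranked variables to display (default 30).
#' @return A ggplot of VIP scores with jackknife CIs.
#' @export
plot_vip <- function(vip, top_n = 30) {
  dat <- dplyr::slice_min(vip, .data$rank, n = top_n)
  if (!"selected" %in% names(dat)) dat$selected <- TRUE
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$variable, -.data$rank),
    y = .data$vip, colour = .data$selected)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower,
                                        ymax = .data$ci_upper),
                           width = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "VIP score (jackknife 95% CI)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method generics::tidy
tidy.oplsda <- function(x, ...) {
  tibble::tibble(
    variable = names(x$w),
    weight = unname(x$w),
    loading = unname(x$p),
    vip = unname(sqrt(length(x$w) * x$w^2 / sum(x$w^2)))
  )
}

#' @exportS3Method generics::glance
glance.oplsda <- function(x, ...) {
  tibble::tibble(
    r2y = x$r2y,
    q2y = x$q2y,
    n_ortho = x$n_ortho,
    nobs = nrow(x$x),
    n_variables = ncol(x$x)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.oplsda <- function(object, ...) {
  dat <- tibble::tibble(
    t_pred = object$t,
    t_ortho = if (object$n_ortho > 0) object$t_o[, 1] else
      seq_along(object$t),
    class = object$y_levels[ifelse(object$y < 0, 1L, 2L)]
  )
  ylab <- if (object$n_ortho > 0) "First orthogonal score" else
    "Sample index"
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t_pred, y = .data$t_ortho,
                                    colour = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Predictive score t[1]", y = ylab,
                  title = sprintf("OPLS-DA scores (R2Y = %.3f)",
                                  object$r2y)) +
    ggplot2::theme_minimal()
}
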