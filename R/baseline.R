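#' Build the baseline design matrix
#'
#' Concatenates the [ts_features()] vector of every feature-matrix row (46
#' timeseries x 24 features = 1104 columns) and, when requested, the two
#' metadata columns (age in weeks, binary birth cohort) into one row per
#' video: length 1106 with metadata, 1104 without. Columns are returned
#' unscaled; the fitting routines standardize with training-split statistics.
#'
#' @param fm_list List of [feature_matrix()] objects (or `46 x n` matrices).
#' @param meta Optional data.frame with `age_weeks` and `cohort` aligned with
#'   `fm_list` (required when `include_meta = TRUE`).
#' @param include_meta Append the metadata columns (default TRUE).
#' @return Numeric matrix `n_videos x 1106` (or `x 1104`).
#' @export
build_design <- function(fm_list, meta = NULL, include_meta = TRUE) {
  if (include_meta && is.null(meta))
    stop("metadata required when include_meta = TRUE")
  rows <- lapply(fm_list, function(fm) {
    vals <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
    as.vector(apply(vals, 1, ts_features))   # 24-feature blocks, row-major
  })
  X <- do.call(rbind, rows)
  nmf <- names(ts_features(stats::rnorm(50)))
  colnames(X) <- as.vector(t(outer(feature_row_names(), nmf, paste, sep = ".")))
  if (include_meta) {
    X <- cbind(X, age_weeks = meta$age_weeks,
               cohort = as.numeric(meta$cohort == "preterm"))
  }
  X
}

# 85/15 group-disjoint stratified split of row indices
.split_85_15 <- function(groups, y, seed) {
  set.seed(seed)
  glab <- vapply(split(y, groups), max, 0)
  gnames <- names(glab)
  test_g <- character(0)
  for (cls in unique(glab)) {
    gs <- sample(gnames[glab == cls])
    sizes <- vapply(split(seq_along(groups), groups)[gs], length, 0L)
    k <- which(cumsum(sizes) >= 0.15 * sum(sizes))[1]
    test_g <- c(test_g, gs[seq_len(k)])
  }
  test <- which(groups %in% test_g)
  list(train = setdiff(seq_along(groups), test), test = test)
}

.standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(mu = mu, sd = sdv)
}

.standardize_apply <- function(X, st)
  sweep(sweep(X, 2, st$mu), 2, st$sd, "/")

# inner 5-fold grid search over inverse-regularisation strengths C,
# fitted with ridge-penalised logistic regression (glmnet, alpha = 0);
# glmnet's lambda corresponds to 1 / (C * n)
.fit_ridge_cv <- function(X, y, Cs = 10^seq(-3, 3), n_folds = 5, seed = 1) {
  set.seed(seed)
  n <- nrow(X)
  lambdas <- sort(1 / (Cs * n), decreasing = TRUE)
  folds <- sample(rep(seq_len(n_folds), length.out = n))
  auc_grid <- matrix(NA_real_, n_folds, length(lambdas))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
    st <- .standardize_fit(X[tr, , drop = FALSE])
    fit <- glmnet::glmnet(.standardize_apply(X[tr, , drop = FALSE], st), y[tr],
                          family = "binomial", alpha = 0, lambda = lambdas,
                          standardize = FALSE)
    pr <- stats::predict(fit, .standardize_apply(X[!tr, , drop = FALSE], st),
                         s = lambdas, type = "response")
    auc_grid[f, ] <- apply(pr, 2, function(p)
      tryCatch(auc_roc(p, y[!tr]), error = function(e) NA))
  }
  mean_auc <- colMeans(auc_grid, na.rm = TRUE)
  best <- which.max(mean_auc)
  st <- .standardize_fit(X)
  fit <- glmnet::glmnet(.standardize_apply(X, st), y, family = "binomial",
                        alpha = 0, lambda = lambdas, standardize = FALSE)
  list(fit = fit, st = st, lambda = lambdas[best],
       C = 1 / (lambdas[best] * n))
}

#' l2-regularised logistic-regression baseline
#'
#' The comparison model: canonical time-series features with ridge logistic
#' regression. Runs repeated 85/15 group-disjoint stratified splits; within
#' each training set the inverse regularisation strength is chosen from a
#' log-spaced grid (10^-3 to 10^3, decade steps) by nested 5-fold
#' cross-validation on AUC, and the test AUC of the refitted model is
#' reported. Columns are z-scored with training-split statistics.
#'
#' @param X Design matrix from [build_design()].
#' @param y Binary labels.
#' @param groups Group (infant) id per row; videos of one infant never span
#'   the train/test divide.
#' @param n_repeats Number of repeated splits (default 25).
#' @param Cs Grid of inverse regularisation strengths.
#' @param seed Base seed.
#' @return List with `auc` (per-repeat data.frame: repeat_id, auc, C) and
#'   `summary` (mean, sd).
#' @export
fit_baseline <- function(X, y, groups, n_repeats = 25L, Cs = 10^seq(-3, 3),
                         seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes required")
  rows <- lapply(seq_len(n_repeats), function(r) {
    sp <- .split_85_15(groups, y, seed + r)
    cv <- .fit_ridge_cv(X[sp$train, , drop = FALSE], y[sp$train], Cs,
                        seed = seed + 100 + r)
    pr <- stats::predict(cv$fit,
                         .standardize_apply(X[sp$test, , drop = FALSE], cv$st),
                         s = cv$lambda, type = "response")[, 1]
    data.frame(repeat_id = r,
               auc = tryCatch(auc_roc(pr, y[sp$test]),
                              error = function(e) NA_real_),
               C = cv$C)
  })
  auc <- do.call(rbind, rows)
  list(auc = auc,
       summary = c(mean = mean(auc$auc, na.rm = TRUE),
                   sd = stats::sd(auc$auc, na.rm = TRUE)))
}

# Nystroem approximation of the RBF kernel feature map: landmarks sampled
# from the training rows; map(x) = K(x, L) U diag(1/sqrt(e)) from the
# eigendecomposition of K(L, L)
.nystroem_fit <- function(X, n_components = 100, gamma = 1 / ncol(X),
                          seed = 1) {
  set.seed(seed)
  m <- min(n_components, nrow(X))
  if (m < n_components)
    warning("n_components capped at the number of training rows (", m, ")")
  idx <- sample.int(nrow(X), m)
  L <- X[idx, , drop = FALSE]
  Kmm <- exp(-gamma * as.matrix(stats::dist(L))^2)
  eg <- eigen(Kmm, symmetric = TRUE)
  keep <- eg$values > 1e-10
  proj <- eg$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[keep]), sum(keep))
  list(L = L, gamma = gamma, proj = proj)
}

.nystroem_apply <- function(ny, X) {
  d2 <- outer(rowSums(X^2), rowSums(ny$L^2), "+") - 2 * X %*% t(ny$L)
  exp(-ny$gamma * pmax(d2, 0)) %*% ny$proj
}

#' Nystroem kernelised logistic-regression baseline
#'
#' Nonlinear variant of [fit_baseline()]: features are mapped through a
#' Nystroem approximation of the RBF kernel (default 100 components,
#' bandwidth `1 / n_features`) before the same ridge logistic pipeline.
#'
#' @inheritParams fit_baseline
#' @param n_components Nystroem landmark count (capped at the training size
#'   with a warning).
#' @param gamma RBF bandwidth; default `1 / ncol(X)`.
#' @return As [fit_baseline()].
#' @export
fit_kernel_baseline <- function(X, y, groups, n_repeats = 25L,
                                Cs = 10^seq(-3, 3), n_components = 100L,
                                gamma = 1 / ncol(X), seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes required")
  rows <- lapply(seq_len(n_repeats), function(r) {
    sp <- .split_85_15(groups, y, seed + r)
    st <- .standardize_fit(X[sp$train, , drop = FALSE])
    Xtr <- .standardize_apply(X[sp$train, , drop = FALSE], st)
    Xte <- .standardize_apply(X[sp$test, , drop = FALSE], st)
    ny <- .nystroem_fit(Xtr, n_components, gamma, seed = seed + 200 + r)
    Ztr <- .nystroem_apply(ny, Xtr)
    Zte <- .nystroem_apply(ny, Xte)
    cv <- .fit_ridge_cv(Ztr, y[sp$train], Cs, seed = seed + 300 + r)
    pr <- stats::predict(cv$fit, .standardize_apply(Zte, cv$st),
                         s = cv$lambda, type = "response")[, 1]
    data.frame(repeat_id = r,
               auc = tryCatch(auc_roc(pr, y[sp$test]),
                              error = function(e) NA_real_),
               C = cv$C)
  })
  auc <- do.call(rbind, rows)
  list(auc = auc,
       summary = c(mean = mean(auc$auc, na.rm = TRUE),
                   sd = stats::sd(auc$auc, na.rm = TRUE)))
}
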