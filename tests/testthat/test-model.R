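test_that("attention pooling matches a brute-force oracle", {
  # independent elementwise evaluation of the three attention equations
  oracle <- function(M, W, b, u) {
    s <- nrow(M); d <- ncol(M)
    alpha <- numeric(s)
    v <- numeric(d)
    for (c_ in seq_len(s)) {
      uc <- numeric(d)
      for (i in seq_len(d)) {
        acc <- b[i]
        for (j in seq_len(d)) acc <- acc + W[i, j] * M[c_, j]
        uc[i] <- tanh(acc)
      }
      dot <- 0
      for (i in seq_len(d)) dot <- dot + uc[i] * u[i]
      alpha[c_] <- 1 / (1 + exp(-dot))
    }
    for (c_ in seq_len(s)) v <- v + alpha[c_] * M[c_, ]
    list(v = v / s, alpha = alpha)
  }
  set.seed(6)
  for (rep in 1:10) {
    s <- sample(1:5, 1); d <- sample(2:8, 1)
    M <- matrix(rnorm(s * d), s, d)
    W <- matrix(rnorm(d * d), d, d)
    b <- rnorm(d); u <- rnorm(d)
    got <- attention_pool(M, W, b, u)
    want <- oracle(M, W, b, u)
    expect_lt(max(abs(got$v - want$v)), 1e-6)
    expect_lt(max(abs(got$alpha - want$alpha)), 1e-6)
    expect_true(all(got$alpha >= 0 & got$alpha <= 1))
  }
  # s = 1: v = alpha_1 m_1
  M1 <- matrix(rnorm(4), 1, 4)
  got1 <- attention_pool(M1, diag(4), rep(0, 4), rep(0.3, 4))
  expect_equal(got1$v, as.vector(M1) * got1$alpha)
  # identical clips share one weight
  M3 <- matrix(rep(rnorm(4), each = 3), 3, 4)
  got3 <- attention_pool(M3, diag(4), rep(0, 4), rnorm(4))
  expect_equal(got3$alpha[1], got3$alpha[2])
  expect_equal(got3$v, M3[1, ] * got3$alpha[1])
})

test_that("the convolutional backbone has the stated shapes", {
  ctrl <- gma_control(use_meta = FALSE)
  fit <- fake_fit(ctrl)
  clips <- make_clips(small_fm())[1:3]
  cb <- conv_backbone(fit, clips)
  expect_equal(cb$stage_dims, c(32, 8, 2))
  expect_identical(dim(cb$flat), c(3L, 128L))    # 2 timesteps x 64 filters
  expect_identical(dim(cb$M), c(3L, 64L))
  expect_error(conv_backbone(fit, list(matrix(0, 100, 46))), "128")
  # zero weights give zero embeddings
  z <- fit
  for (l in 1:3) z$params$conv[[l]]$W[] <- 0
  z$params$fc$W[] <- 0; z$params$fc$b[] <- 0
  for (l in 1:3) {
    z$params$conv[[l]]$b[] <- 0
    z$params$conv[[l]]$beta[] <- 0
  }
  expect_equal(max(abs(conv_backbone(z, clips)$M)), 0)
})

test_that("causal convolutions never look ahead", {
  ctrl <- gma_control(use_meta = FALSE)
  fit <- fake_fit(ctrl)
  clip <- make_clips(small_fm())[[1]]
  X0 <- t(clip)
  fw0 <- gmascreen:::nn_forward(fit$params, X0, B = 1, groups = 1L,
                                meta = NULL, cfg = ctrl)
  j <- 60
  clip2 <- clip
  clip2[j, ] <- clip2[j, ] + rnorm(46)
  fw1 <- gmascreen:::nn_forward(fit$params, t(clip2), B = 1, groups = 1L,
                                meta = NULL, cfg = ctrl)
  # stage-1 normalised activations: columns are timesteps
  changed <- which(colSums(abs(fw1$cache$conv[[1]]$xhat -
                                 fw0$cache$conv[[1]]$xhat)) > 1e-12)
  expect_gte(min(changed), j)
})

test_that("inference is deterministic, bounded and permutation-invariant", {
  ctrl <- gma_control(use_meta = FALSE)
  fit <- fake_fit(ctrl)
  fm <- small_fm()
  p1 <- predict_video(fit, fm)
  p2 <- predict_video(fit, fm)
  expect_identical(p1$raw_score, p2$raw_score)
  expect_gt(p1$raw_score, 0); expect_lt(p1$raw_score, 1)
  expect_length(p1$alpha, length(make_clips(fm)))
  # permuting clip order leaves the pooled score unchanged
  clips <- make_clips(fm)
  X <- t(do.call(rbind, clips))
  perm <- sample(length(clips))
  Xp <- t(do.call(rbind, clips[perm]))
  s_a <- gmascreen:::nn_forward(fit$params, X, B = length(clips),
                                groups = rep(1L, length(clips)), meta = NULL,
                                cfg = ctrl)$score
  s_b <- gmascreen:::nn_forward(fit$params, Xp, B = length(clips),
                                groups = rep(1L, length(clips)), meta = NULL,
                                cfg = ctrl)$score
  expect_equal(s_a, s_b, tolerance = 1e-12)
})

test_that("the metadata branch has the stated 2x4 structure", {
  expect_equal(metadata_branch(c(0.5, 1), rep(0, 4), rep(0, 4)), rep(0, 8))
  out <- metadata_branch(c(1.2, 0), rnorm(4), rnorm(4))
  expect_length(out, 8)
  W <- c(1, 2, 3, 4); b <- rep(0, 4)
  expect_equal(metadata_branch(c(2, -1), W, b), c(2 * W, -W))
})

test_that("minority oversampling approximately balances the classes", {
  y <- c(rep(0, 408), rep(1, 76))
  idx <- oversample_indices(y, 5)
  expect_identical(sum(y[idx] == 0), 408L)
  expect_identical(sum(y[idx] == 1), 380L)
  expect_lt(abs(sum(y[idx] == 1) / sum(y[idx] == 0) - 1), 0.1)
  expect_identical(oversample_indices(c(0, 0, 1, 1), 5), 1:4)
})

test_that("early stopping retains the minimum-validation-loss epoch", {
  es <- early_stop(c(1.0, 0.9, 0.95, 0.96), patience = 2)
  expect_identical(es$best_epoch, 2L)
  expect_identical(es$stop_epoch, 4L)
  es2 <- early_stop(c(1, 0.9, 0.8, 0.7), patience = 2)
  expect_identical(es2$best_epoch, 4L)
  expect_identical(es2$stop_epoch, 4L)
})

test_that("Platt scaling is near-identity for calibrated scores and monotone", {
  set.seed(17)
  n <- 1000
  scores <- runif(n, 0.02, 0.98)
  labels <- rbinom(n, 1, scores)
  cal <- fit_platt(scores, labels)
  grid <- seq(0.1, 0.9, by = 0.05)
  expect_lt(max(abs(apply_platt(cal, grid) - grid)), 0.05)
  expect_gt(cal$a, 0)
  expect_true(all(diff(apply_platt(cal, seq(0.01, 0.99, 0.01))) >= 0))
  expect_error(fit_platt(runif(10), rep(1, 10)), "both classes")
  expect_warning(fit_platt(rep(0.4, 20), rep(c(0, 1), 10)), "degenerate")
})

test_that("Platt scaling does not worsen the validation Brier score", {
  set.seed(18)
  n <- 400
  # miscalibrated scores, as produced by training on an oversampled set
  truth <- rbinom(n, 1, 0.16)
  raw <- plogis(qlogis(0.5) + 1.5 * (truth - 0.16) + rnorm(n, 0, 1))
  cal <- fit_platt(raw, truth)
  brier_raw <- mean((raw - truth)^2)
  brier_cal <- mean((apply_platt(cal, raw) - truth)^2)
  expect_lte(brier_cal, brier_raw + 1e-6)
})

test_that("a short fit learns separable data and exposes model methods", {
  set.seed(19)
  mk <- function(amp) {
    v <- matrix(rnorm(46 * 300, 0, 0.02), 46, 300)
    v[13, ] <- v[13, ] + amp * sin(seq_len(300) / 2)
    v[37:46, ] <- abs(v[37:46, ]) %% pi
    v
  }
  feats <- c(lapply(1:6, function(i) mk(0.05)),
             lapply(1:6, function(i) mk(1.0)))
  y <- rep(c(0, 1), each = 6)
  ctrl <- gma_control(max_epochs = 25, patience = 25, eval_stride = 64,
                      oversample_factor = 1, use_meta = FALSE,
                      augment = augment_config(apply_magnitude = FALSE,
                                               apply_warp = FALSE))
  fit <- gma_fit(feats[c(1:4, 7:10)], y[c(1:4, 7:10)],
                 validation = list(features = feats[c(5, 6, 11, 12)],
                                   y = y[c(5, 6, 11, 12)]),
                 control = ctrl, seed = 20)
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_s3_class(fit, "gma_fit")
  expect_output(print(fit), "clip-attention")
  expect_output(print(summary(fit)), "epochs")
  expect_type(coef(fit), "list")
  expect_length(residuals(fit), 4)
  pr <- predict(fit, feats[c(5, 11)])
  expect_identical(nrow(pr), 2L)
  expect_true(all(pr$calibrated_prob >= 0 & pr$calibrated_prob <= 1))
  # training with both classes is required
  expect_error(gma_fit(feats[1:3], c(0, 0, 0),
                       validation = list(features = feats[4], y = 0),
                       control = ctrl), "both classes")
})

test_that("label smoothing maps targets to 0.05 and 0.95", {
  ls <- 0.1
  expect_equal(c(0, 1) * (1 - ls) + ls / 2, c(0.05, 0.95))
})

test_that("saliency maps match finite differences and shapes", {
  ctrl <- gma_control(use_meta = FALSE)
  fit <- fake_fit(ctrl, seed = 23)
  fm <- small_fm(n_frames = 300, seed = 24)
  sal <- saliency(fit, fm)
  n_clips <- length(make_clips(fm))
  expect_identical(dim(sal$map), c(46L, n_clips))
  expect_length(sal$clip_totals, n_clips)
  expect_length(sal$point_average, 18)
  # central finite differences on the raw video score
  vals <- fm$values
  score_of <- function(v) {
    fmv <- feature_matrix(v, "fd", n_frames = ncol(v))
    predict_video(fit, fmv)$raw_score
  }
  vf <- gmascreen:::.video_forward(fit$params, vals, NULL, ctrl,
                                   keep_cache = TRUE)
  bw <- gmascreen:::nn_backward(fit$params, vf$cache,
                                vf$score * (1 - vf$score), ctrl,
                                want_dX = TRUE)
  # map stacked clip-gradient columns back to source frames for frames that
  # appear in exactly one clip (the first stride of the first clip)
  set.seed(25)
  eps <- 1e-4
  errs <- c()
  for (k in 1:10) {
    i <- sample(36, 1); j <- sample(8, 1)   # first clip only covers frame j<9
    v1 <- vals; v1[i, j] <- v1[i, j] + eps
    v2 <- vals; v2[i, j] <- v2[i, j] - eps
    num <- (score_of(v1) - score_of(v2)) / (2 * eps)
    ana <- bw$dX[i, j]
    errs <- c(errs, abs(num - ana) / max(1e-10, abs(num), abs(ana)))
  }
  expect_lt(max(errs), 1e-3)
  # zero-weight model has zero saliency
  z <- fit
  for (l in 1:3) z$params$conv[[l]]$W[] <- 0
  z$params$fc$W[] <- 0
  sal0 <- saliency(z, fm)
  expect_equal(max(abs(sal0$map)), 0)
})

test_that("QC-failed videos are refused at prediction time", {
  fit <- fake_fit()
  fm <- small_fm()
  attr(fm, "qc") <- list(pass = FALSE, fraction = 0.5)
  expect_error(predict_video(fit, fm), "quality control")
})
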