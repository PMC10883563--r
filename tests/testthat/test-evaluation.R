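test_that("grouped stratified splits respect groups, strata and seeds", {
  lab <- data.frame(video_id = sprintf("v%03d", 1:100),
                    infant_id = sprintf("i%03d", 1:100),
                    gms_binary = rep(c(1, 0), c(16, 84)))
  sp <- make_splits(lab, n_repeats = 3, seed = 1)
  expect_length(sp, 3)
  s1 <- sp[[1]]
  expect_setequal(c(s1$train, s1$val, s1$test), lab$video_id)
  n_abn_test <- sum(lab$gms_binary[match(s1$test, lab$video_id)])
  expect_gte(length(s1$test), 13); expect_lte(length(s1$test), 17)
  expect_gte(n_abn_test, 2); expect_lte(n_abn_test, 3)
  # seeds differ -> at least one split differs
  sp2 <- make_splits(lab, n_repeats = 1, seed = 99)
  expect_false(identical(sort(sp[[1]]$test), sort(sp2[[1]]$test)))
  # same seed -> identical plan
  expect_identical(make_splits(lab, n_repeats = 3, seed = 1), sp)
})

test_that("an infant's two videos always share a subset", {
  lab <- data.frame(video_id = sprintf("v%03d", 1:60),
                    infant_id = sprintf("i%03d", rep(1:30, each = 2)),
                    gms_binary = rep(rbinom(30, 1, 0.2), each = 2))
  sp <- make_splits(lab, n_repeats = 25, seed = 2)
  for (r in seq_along(sp)) {
    subset_of <- rep(c("train", "val", "test"),
                     c(length(sp[[r]]$train), length(sp[[r]]$val),
                       length(sp[[r]]$test)))
    names(subset_of) <- c(sp[[r]]$train, sp[[r]]$val, sp[[r]]$test)
    by_inf <- split(subset_of[lab$video_id], lab$infant_id)
    expect_true(all(vapply(by_inf, function(v) length(unique(v)) == 1, TRUE)))
  }
  # a group larger than the whole test set is an error
  lab_big <- data.frame(video_id = sprintf("v%02d", 1:20),
                        infant_id = c(rep("big", 12), sprintf("i%02d", 13:20)),
                        gms_binary = rep(c(0, 1), 10))
  expect_error(make_splits(lab_big, n_repeats = 1), "larger than the test")
})

test_that("metrics match their confusion-matrix definitions", {
  perfect <- compute_metrics(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$balanced_accuracy, 1)
  # TP = 3, FN = 1, TN = 12, FP = 4
  labels <- rep(c(1, 0), c(4, 16))
  scores <- c(rep(0.9, 3), 0.1, rep(0.8, 4), rep(0.2, 12))
  m <- compute_metrics(scores, labels)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.75)
  expect_equal(m$ppv, 3 / 7)
  expect_equal(m$npv, 12 / 13)
  expect_equal(m$balanced_accuracy, 0.75)
  # chance scores give AUC near 0.5 at large n
  set.seed(31)
  m2 <- compute_metrics(runif(4000), rbinom(4000, 1, 0.3))
  expect_lt(abs(m2$auc - 0.5), 0.05)
  expect_warning(m3 <- compute_metrics(runif(5), rep(1, 5)), "single-class")
  expect_true(is.na(m3$auc))
  expect_equal(m3$sensitivity, sum(runif(5) >= 0) / 5, tolerance = 1)
})

test_that("trapezoidal AUC equals rank-based AUC and pROC on random data", {
  rank_auc <- function(s, y) {
    r <- rank(s)
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  set.seed(32)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), sample(1:3, 1))   # ties included
    expect_equal(auc_roc(s, y), rank_auc(s, y), tolerance = 1e-12)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(33)
    y <- rbinom(200, 1, 0.3); s <- runif(200)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_roc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("cross-repeat label aggregation is majority with abnormal ties", {
  pr <- data.frame(video_id = c("a", "a", "a", "b", "b", "c"),
                   label = c(1, 1, 0, 1, 0, 0),
                   calibrated_prob = c(0.9, 0.8, 0.2, 0.6, 0.4, 0.1))
  agg <- aggregate_labels(pr)
  expect_equal(agg$label[agg$video_id == "a"], 1)    # majority
  expect_equal(agg$label[agg$video_id == "b"], 1)    # tie -> abnormal
  expect_equal(agg$label[agg$video_id == "c"], 0)    # single appearance
  expect_equal(agg$median_score[agg$video_id == "a"], 0.8)
  # invariant to repeat ordering
  agg2 <- aggregate_labels(pr[sample(nrow(pr)), ])
  expect_equal(agg[order(agg$video_id), ], agg2[order(agg2$video_id), ],
               ignore_attr = TRUE)
  agg3 <- aggregate_labels(pr, all_ids = c("a", "b", "c", "d"))
  expect_identical(attr(agg3, "excluded"), "d")
})

test_that("saliency clip displacement statistics match hand arithmetic", {
  # two videos x few clips with a controlled displacement structure
  mk_fm <- function(step) {
    v <- matrix(0, 46, 96)
    # move every point +step in x during the second half
    v[seq(1, 35, 2), 49:96] <- step
    v[37:46, ] <- 1
    v
  }
  fm1 <- mk_fm(0.4); fm2 <- mk_fm(0)
  t_clip <- 16L; stride <- 8L
  n_clips <- (96 - t_clip) / stride + 1
  sal1 <- seq_len(n_clips)              # later clips most salient
  sal2 <- rep(0.5, n_clips)
  res <- saliency_clip_analysis(list(sal1, sal2), list(fm1, fm2),
                                t = t_clip, stride = stride)
  expect_true(nrow(res$high) >= 1 && nrow(res$low) >= 1)
  # mean displacement of a fully displaced clip is |step|/2 around the mean
  d_in_half <- 0.4 / 2
  expect_equal(max(res$high$mean_disp), d_in_half)
  # frozen video: zero displacement in every clip
  expect_true(all(res$low$mean_disp[res$low$video == 2] == 0))
  # equal saliency everywhere: both sets nonempty, difference zero
  same <- saliency_clip_analysis(list(rep(1, n_clips), rep(1, n_clips)),
                                 list(fm2, fm2), t = t_clip, stride = stride)
  expect_gt(nrow(same$high), 0); expect_gt(nrow(same$low), 0)
  expect_equal(same$median_diff_mean, 0)
  expect_error(saliency_clip_analysis(list(1:3), list(fm1[, 1:32]), t = 16,
                                      stride = 8), "at least 10")
})

test_that("a miniature cross-validation run produces coherent outputs", {
  set.seed(34)
  mk <- function(amp) {
    v <- matrix(rnorm(46 * 300, 0, 0.02), 46, 300)
    v[13, ] <- v[13, ] + amp * sin(seq_len(300) / 2)
    v[37:46, ] <- abs(v[37:46, ]) %% pi
    v
  }
  n <- 14
  y <- rep(c(0, 1), each = n / 2)
  feats <- lapply(y, function(cl) mk(if (cl == 1) 1 else 0.05))
  lab <- data.frame(video_id = sprintf("v%02d", 1:n),
                    infant_id = sprintf("i%02d", 1:n),
                    gms_binary = y)
  names(feats) <- lab$video_id
  ctrl <- gma_control(max_epochs = 8, patience = 8, eval_stride = 128,
                      oversample_factor = 1, use_meta = FALSE,
                      augment = augment_config(apply_magnitude = FALSE,
                                               apply_warp = FALSE))
  res <- run_cv(feats, lab, control = ctrl, n_repeats = 2, seed = 35)
  expect_identical(nrow(res$metrics), 2L)
  expect_true(all(c("auc", "balanced_accuracy") %in% names(res$metrics)))
  expect_true(all(res$predictions$calibrated_prob >= 0 &
                    res$predictions$calibrated_prob <= 1))
  agg <- aggregate_labels(res$predictions, all_ids = lab$video_id)
  expect_true(all(agg$label %in% c(0, 1)))
})
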