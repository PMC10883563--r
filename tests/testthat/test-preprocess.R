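test_that("confidence filtering uses a strictly-below rule", {
  ts <- skeleton_ts(n_frames = 10)
  ts$confidence[3, 1] <- 0.19
  ts$confidence[4, 1] <- 0.20
  out <- filter_confidence(ts, 0.2)
  expect_true(is.na(out$x[3, 1]) && is.na(out$y[3, 1]))
  expect_false(is.na(out$x[4, 1]))
  ident <- filter_confidence(skeleton_ts(n_frames = 10))
  expect_equal(ident$x, skeleton_ts(n_frames = 10)$x)
})

test_that("quality control passes at exactly 70% labelled", {
  ts <- skeleton_ts(n_frames = 100)
  expect_true(qc_pass(ts)$pass)
  expect_equal(qc_pass(ts)$fraction, 1.0)
  # knock out points to reach exactly 0.70, then one more to fall below
  ts2 <- ts
  ts2$x[, 1:5] <- NA; ts2$y[, 1:5] <- NA
  ts2$x[1:40, 6] <- NA; ts2$y[1:40, 6] <- NA   # 1 - (5*100+40)/1800 = 0.70
  q <- qc_pass(ts2)
  expect_equal(q$fraction, 0.70)
  expect_true(q$pass)
  ts2$x[1:18, 7] <- NA
  expect_false(qc_pass(ts2)$pass)
})

test_that("the torso frame has the stated centre, axes and unit length", {
  ts <- skeleton_ts(n_frames = 5, scale_px = 200)
  tf <- torso_frame(ts, 1)
  expect_equal(tf$unit_length, 200)
  # proximal-distal axis points from mid-hip toward mid-shoulder (up, -y)
  expect_equal(as.vector(tf$axes["proximal_distal", ]), c(0, -1))
  # axes rotate with the body
  ts30 <- skeleton_ts(n_frames = 5, theta = rep(pi / 6, 5))
  tf30 <- torso_frame(ts30, 1)
  expect_equal(sum(tf30$axes["proximal_distal", ] *
                     tf30$axes["medial_lateral", ]), 0, tolerance = 1e-12)
  expect_equal(abs(sum(tf$axes["proximal_distal", ] *
                         tf30$axes["proximal_distal", ])), cos(pi / 6))
  # degenerate: crown on the mid-hip
  bad <- ts
  mid_hip <- c(mean(bad$x[1, c("left_hip", "right_hip")]),
               mean(bad$y[1, c("left_hip", "right_hip")]))
  bad$x[, "crown"] <- mid_hip[1]; bad$y[, "crown"] <- mid_hip[2]
  expect_error(torso_frame(bad, 1), "degenerate")
})

test_that("the whole-body ellipse removes points by the 3x2 unit rule", {
  ts <- skeleton_ts(n_frames = 3, scale_px = 100)
  tf <- torso_frame(ts, 1)
  ctr <- tf$center; u <- tf$unit_length
  pd <- tf$axes["proximal_distal", ]; ml <- tf$axes["medial_lateral", ]
  # frame 1: wrist at the torso centre -> kept
  ts$x[1, "left_wrist"] <- ctr[1]; ts$y[1, "left_wrist"] <- ctr[2]
  # frame 2: 3.1 unit lengths purely proximal -> (3.1/3)^2 > 1, removed
  p2 <- ctr + 3.1 * u * pd
  ts$x[2, "left_wrist"] <- p2[1]; ts$y[2, "left_wrist"] <- p2[2]
  # frame 3: (2.0 pd, 1.0 ml): (2/3)^2 + (1/2)^2 = 0.694 -> kept
  p3 <- ctr + 2.0 * u * pd + 1.0 * u * ml
  ts$x[3, "left_wrist"] <- p3[1]; ts$y[3, "left_wrist"] <- p3[2]
  out <- remove_outliers_global(ts)
  expect_false(is.na(out$x[1, "left_wrist"]))
  expect_true(is.na(out$x[2, "left_wrist"]))
  expect_false(is.na(out$x[3, "left_wrist"]))
})

test_that("per-point ellipses remove gross jumps but keep still points", {
  set.seed(8)
  n <- 60
  ts <- skeleton_ts(n_frames = n, scale_px = 100)
  # jitter the left wrist a little, then displace one frame enormously
  ts$x[, "left_wrist"] <- ts$x[, "left_wrist"] + rnorm(n, 0, 1)
  ts$y[, "left_wrist"] <- ts$y[, "left_wrist"] + rnorm(n, 0, 1)
  ts$x[17, "left_wrist"] <- ts$x[17, "left_wrist"] + 150   # 1.5 unit lengths
  out <- remove_outliers_pointwise(ts)
  expect_true(is.na(out$x[17, "left_wrist"]))
  expect_false(anyNA(out$x[-17, "left_wrist"]))
  # a perfectly still point survives via the semi-axis floor
  expect_false(anyNA(out$x[, "right_wrist"]))
})

test_that("outlier stages are idempotent", {
  set.seed(9)
  sv <- clean_sim(0, duration_s = 15, mislabel_rate = 0.01)
  ts <- filter_confidence(sv$ts)
  g1 <- remove_outliers_global(ts)
  g2 <- remove_outliers_global(g1)
  expect_identical(is.na(g1$x), is.na(g2$x))
  st <- pointwise_stats(list(g1))
  p1 <- remove_outliers_pointwise(g1, dataset_stats = st)
  p2 <- remove_outliers_pointwise(p1, dataset_stats = st)
  expect_identical(is.na(p1$x), is.na(p2$x))
})

test_that("gap filling interpolates short gaps linearly, never alters data", {
  ts <- skeleton_ts(n_frames = 20)
  ts$x[, "crown"] <- 0:19
  ts$x[2:4, "crown"] <- NA                      # 3-frame interior gap
  ts$x[10:14, "crown"] <- NA                    # exactly 5 frames
  obs_y <- ts$y
  out <- fill_gaps(ts)
  expect_equal(out$x[2:4, "crown"], c(1, 2, 3))
  expect_equal(out$x[10:14, "crown"], 9:13)
  expect_false(anyNA(out$x))
  expect_equal(out$y[!is.na(obs_y)], obs_y[!is.na(obs_y)])
})

test_that("long gaps are imputed from correlated channels", {
  set.seed(10)
  n <- 80
  ts <- skeleton_ts(n_frames = n)
  base <- cumsum(rnorm(n))
  ts$x[, "left_wrist"] <- 300 + base
  ts$x[, "crown"] <- 2 * ts$x[, "left_wrist"] - 50    # exactly collinear
  truth <- ts$x[30:35, "crown"]
  ts$x[30:35, "crown"] <- NA                          # 6-frame gap
  out <- fill_gaps(ts)
  expect_lt(max(abs(out$x[30:35, "crown"] - truth)), 1e-3)
  # an all-missing channel is a named error
  bad <- skeleton_ts(n_frames = 20)
  bad$x[, "chin"] <- NA
  expect_error(fill_gaps(bad), "chin")
})

test_that("rotation alignment verticalises the midline and is an isometry", {
  ts0 <- skeleton_ts(n_frames = 4)
  expect_equal(align_rotation(ts0)$x, ts0$x, tolerance = 1e-12)

  ts <- skeleton_ts(n_frames = 4, theta = rep(pi / 6, 4))
  out <- align_rotation(ts)
  msx <- rowMeans(out$x[, c("left_shoulder", "right_shoulder")])
  mhx <- rowMeans(out$x[, c("left_hip", "right_hip")])
  msy <- rowMeans(out$y[, c("left_shoulder", "right_shoulder")])
  mhy <- rowMeans(out$y[, c("left_hip", "right_hip")])
  expect_lt(max(abs(atan2(mhx - msx, mhy - msy))), 1e-9)
  expect_true(all(mhy > msy))                  # mid-hip below mid-shoulder
  d_in <- dist(cbind(ts$x[1, ], ts$y[1, ]))
  d_out <- dist(cbind(out$x[1, ], out$y[1, ]))
  expect_equal(as.vector(d_out), as.vector(d_in), tolerance = 1e-9)
})

test_that("alignment recovers the synthetic camera rotation to < 1 degree", {
  cfg <- synth_config(duration_s = 10, camera_rot_amp = 15,
                      camera_drift_amp = 20, occlusion_rate = 0,
                      mislabel_rate = 0)
  sv <- simulate_video(cfg, 0, seed = 13)
  ts <- sv$ts
  msx <- rowMeans(ts$x[, c("left_shoulder", "right_shoulder")])
  mhx <- rowMeans(ts$x[, c("left_hip", "right_hip")])
  msy <- rowMeans(ts$y[, c("left_shoulder", "right_shoulder")])
  mhy <- rowMeans(ts$y[, c("left_hip", "right_hip")])
  ang_pre <- atan2(mhx - msx, mhy - msy)
  expect_lt(max(abs(ang_pre + sv$truth$cam_theta)) * 180 / pi, 1e-6)
  out <- align_rotation(ts)
  msx <- rowMeans(out$x[, c("left_shoulder", "right_shoulder")])
  mhx <- rowMeans(out$x[, c("left_hip", "right_hip")])
  msy <- rowMeans(out$y[, c("left_shoulder", "right_shoulder")])
  mhy <- rowMeans(out$y[, c("left_hip", "right_hip")])
  expect_lt(max(abs(atan2(mhx - msx, mhy - msy))) * 180 / pi, 1)
})

test_that("scaling normalises to unit length, centres mid-hip, zoom-invariant", {
  ts <- skeleton_ts(n_frames = 6, scale_px = 200)
  out <- scale_and_center(ts)
  mh <- cbind(rowMeans(out$x[, c("left_hip", "right_hip")]),
              rowMeans(out$y[, c("left_hip", "right_hip")]))
  expect_lt(max(abs(mh)), 1e-12)
  u <- sqrt((out$x[, "crown"] - mh[, 1])^2 + (out$y[, "crown"] - mh[, 2])^2)
  expect_equal(unname(u), rep(1, 6))
  doubled <- ts
  doubled$x <- ts$x * 2; doubled$y <- ts$y * 2
  out2 <- scale_and_center(doubled)
  expect_equal(out2$x, out$x, tolerance = 1e-12)
})

test_that("framerate normalisation lands on the target grid", {
  set.seed(12)
  n <- 5400
  ts <- skeleton_ts(n_frames = n, fps = 30)
  ts$x[, "left_knee"] <- sin(seq_len(n) / 40) * 30 + ts$x[1, "left_knee"]
  out <- resample_frames(ts, preprocess_config(target_frames = 4500))
  expect_identical(out$n_frames, 4500L)
  expect_equal(out$fps, 25)
  expect_equal(out$x[, "crown"], unname(rep(ts$x[1, "crown"], 4500)))  # constant

  ts25 <- skeleton_ts(n_frames = 100, fps = 25)
  ts25$x[, "chin"] <- cumsum(rnorm(100))
  same <- resample_frames(ts25, preprocess_config(target_frames = 100))
  expect_equal(same$x[, "chin"], ts25$x[, "chin"], tolerance = 1e-9)

  expect_error(resample_frames(skeleton_ts(n_frames = 3),
                               preprocess_config(target_frames = 10)),
               "at least 4")
})

test_that("joint angles follow the interior-angle convention", {
  x <- matrix(0, 1, 18, dimnames = list(NULL, body_points()))
  y <- x
  # collinear hip-knee-heel on the left leg -> knee angle pi
  x[1, "left_hip"] <- 0; y[1, "left_hip"] <- 0
  x[1, "left_knee"] <- 0; y[1, "left_knee"] <- 1
  x[1, "left_heel"] <- 0; y[1, "left_heel"] <- 2
  # perpendicular segments at the left elbow -> pi/2
  x[1, "left_elbow"] <- 0; y[1, "left_elbow"] <- 0
  x[1, "left_shoulder"] <- 1; y[1, "left_shoulder"] <- 0
  x[1, "left_wrist"] <- 0; y[1, "left_wrist"] <- 1
  x[1, "left_bigtoe"] <- 1; y[1, "left_bigtoe"] <- 2.5
  suppressWarnings(ang <- joint_angles(x, y))
  expect_identical(ncol(ang), 10L)
  expect_equal(unname(ang[1, "left_knee_angle"]), pi)
  expect_equal(unname(ang[1, "left_elbow_angle"]), pi / 2)
  expect_true(all(ang >= 0 & ang <= pi))
  # angles are invariant to the coordinate normalisation
  ts <- skeleton_ts(n_frames = 5, theta = seq(0, 0.5, length.out = 5))
  a_raw <- joint_angles(ts$x, ts$y)
  al <- scale_and_center(align_rotation(ts))
  a_norm <- joint_angles(al$x, al$y)
  expect_equal(a_norm, a_raw, tolerance = 1e-9)
})

test_that("the full pipeline yields a valid feature matrix", {
  sv <- clean_sim(0, duration_s = 20, occlusion_rate = 0.5)
  fm <- preprocess_video(sv$ts, preprocess_config(target_frames = 500))
  expect_s3_class(fm, "feature_matrix")
  expect_identical(dim(fm$values), c(46L, 500L))
  expect_true(all(fm$values[37:46, ] >= 0 & fm$values[37:46, ] <= pi))
  # mid-hip coordinate rows are identically zero (centred)
  mh_x <- (fm$values["left_hip_x", ] + fm$values["right_hip_x", ]) / 2
  mh_y <- (fm$values["left_hip_y", ] + fm$values["right_hip_y", ]) / 2
  expect_lt(max(abs(c(mh_x, mh_y))), 1e-9)
})

test_that("preprocessing is invariant to global similarity transforms", {
  sv <- clean_sim(0, duration_s = 16, seed = 14)
  pc <- preprocess_config(target_frames = 400)
  fm0 <- preprocess_video(sv$ts, pc)
  phi <- 0.4; s <- 1.7; tr <- c(123, -45)
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  ts2 <- sv$ts
  for (j in 1:18) {
    p <- s * R %*% rbind(sv$ts$x[, j], sv$ts$y[, j]) + tr
    ts2$x[, j] <- p[1, ]; ts2$y[, j] <- p[2, ]
  }
  fm1 <- preprocess_video(ts2, pc)
  expect_lt(max(abs(fm1$values - fm0$values)), 1e-6)
})

test_that("videos failing quality control are refused", {
  sv <- clean_sim(0, duration_s = 10)
  ts <- sv$ts
  drop <- seq_len(floor(ts$n_frames * 0.95))
  ts$confidence[drop, 1:8] <- 0.05             # ~10.4/18 points labelled
  expect_error(preprocess_video(ts, preprocess_config(target_frames = 200)),
               "quality control")
  expect_warning(
    fm <- preprocess_video(ts, preprocess_config(target_frames = 200),
                           enforce_qc = FALSE),
    "quality control")
  expect_false(attr(fm, "qc")$pass)
})
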