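test_that("the base skeleton has the stated geometry", {
  sk <- make_skeleton(200)
  mid_hip <- (sk[, "left_hip"] + sk[, "right_hip"]) / 2
  expect_equal(sqrt(sum((sk[, "crown"] - mid_hip)^2)), 200)
  # left/right pairs mirrored about the midline (x = crown x)
  prs <- gmascreen:::.bp_pairs()
  for (i in seq_len(nrow(prs))) {
    expect_equal(sk["x", prs[i, 1]], -sk["x", prs[i, 2]])
    expect_equal(sk["y", prs[i, 1]], sk["y", prs[i, 2]])
  }
  mid_sh <- (sk[, "left_shoulder"] + sk[, "right_shoulder"]) / 2
  expect_equal(mid_sh["x"], mid_hip["x"])     # midline vertical
  expect_error(make_skeleton(-1))
})

test_that("simulation is deterministic under a seed", {
  cfg <- synth_config(duration_s = 10)
  a <- simulate_video(cfg, 1, seed = 99)
  b <- simulate_video(cfg, 1, seed = 99)
  expect_identical(a$ts$x, b$ts$x)
  expect_identical(a$truth$cam_theta, b$truth$cam_theta)
  c <- simulate_video(cfg, 1, seed = 100)
  expect_false(identical(a$ts$x, c$ts$x))
})

test_that("a degenerate config yields full confidence and a fixed midline", {
  sv <- clean_sim(0, duration_s = 10)
  expect_true(all(sv$ts$confidence == 1))
  mid_sh_x <- (sv$ts$x[, "left_shoulder"] + sv$ts$x[, "right_shoulder"]) / 2
  mid_sh_y <- (sv$ts$y[, "left_shoulder"] + sv$ts$y[, "right_shoulder"]) / 2
  mid_hp_x <- (sv$ts$x[, "left_hip"] + sv$ts$x[, "right_hip"]) / 2
  mid_hp_y <- (sv$ts$y[, "left_hip"] + sv$ts$y[, "right_hip"]) / 2
  ang <- atan2(mid_hp_x - mid_sh_x, mid_hp_y - mid_sh_y)
  expect_lt(diff(range(ang)), 1e-9)           # trunk moves rigidly
})

test_that("occlusions sit under the confidence threshold, mislabels above it", {
  cfg <- synth_config(duration_s = 30, occlusion_rate = 2, mislabel_rate = 0.01)
  sv <- simulate_video(cfg, 0, seed = 4)
  conf <- as.vector(sv$ts$confidence)
  expect_true(any(conf < 0.2))
  expect_true(all(conf[conf >= 0.2] >= 0.7))  # bimodal confidence model
})

test_that("dataset generation matches requested prevalence and grouping", {
  cfg <- synth_config(n_videos = 100, p_abnormal = 0.16, duration_s = 2)
  ds <- generate_dataset(cfg, group = TRUE, seed = 7)
  expect_identical(nrow(ds$labels), 100L)
  expect_false(any(duplicated(ds$labels$video_id)))
  n_abn <- sum(ds$labels$gms_binary)
  expect_gte(n_abn, qbinom(0.001, 100, 0.16))
  expect_lte(n_abn, qbinom(0.999, 100, 0.16))
  # videos of one infant share the class label
  by_inf <- split(ds$labels$gms_binary, ds$labels$infant_id)
  expect_true(all(vapply(by_inf, function(v) length(unique(v)) == 1, TRUE)))
  expect_true(any(vapply(by_inf, length, 0L) == 2))

  empty <- generate_dataset(synth_config(n_videos = 0, duration_s = 2))
  expect_identical(nrow(empty$labels), 0L)
  solo <- generate_dataset(cfg, group = FALSE, seed = 7)
  expect_false(any(duplicated(solo$labels$infant_id)))
})

test_that("the normal class carries more fidgety-band power at the knee", {
  # independent periodogram oracle for band power at the left knee
  band_power <- function(v, fps, lo = 0.5, hi = 3) {
    v <- v - mean(v)
    n <- length(v)
    P <- Mod(stats::fft(v))^2 / n
    f <- (seq_len(n) - 1) / n * fps
    sum(P[f >= lo & f <= hi])
  }
  cfg <- synth_config(duration_s = 12, camera_rot_amp = 0,
                      camera_drift_amp = 0, occlusion_rate = 0,
                      mislabel_rate = 0)
  p0 <- p1 <- c()
  set.seed(21)
  for (i in 1:20) {
    v0 <- simulate_video(cfg, 0)
    p0 <- c(p0, band_power(v0$ts$x[, "left_knee"], v0$ts$fps))
  }
  while (length(p1) < 20) {
    v1 <- simulate_video(cfg, 1)
    if (v1$truth$fid_mult < 1)                 # the suppressed variant
      p1 <- c(p1, band_power(v1$ts$x[, "left_knee"], v1$ts$fps))
  }
  expect_gt(mean(p0) - mean(p1), 0)
})
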