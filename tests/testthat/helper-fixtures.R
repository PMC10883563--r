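# shared fixtures, built in code

# a keypoint_ts of the static base skeleton with optional per-frame rotation
# (radians, about the image centre) and translation
skeleton_ts <- function(n_frames = 50, scale_px = 200, fps = 25,
                        theta = rep(0, n_frames), shift = c(0, 0),
                        center = c(320, 240)) {
  sk <- make_skeleton(scale_px)
  xs <- matrix(NA_real_, n_frames, 18)
  ys <- matrix(NA_real_, n_frames, 18)
  for (i in seq_len(n_frames)) {
    R <- matrix(c(cos(theta[i]), sin(theta[i]),
                  -sin(theta[i]), cos(theta[i])), 2, 2)
    pts <- R %*% sk + center + shift
    xs[i, ] <- pts[1, ]
    ys[i, ] <- pts[2, ]
  }
  keypoint_ts("skel", fps, xs, ys, matrix(1, n_frames, 18))
}

# a quick noise-free simulated video (no camera, occlusion or mislabels
# unless overridden)
clean_sim <- function(class = 0, duration_s = 20, seed = 11, ...) {
  args <- utils::modifyList(
    list(duration_s = duration_s, camera_rot_amp = 0, camera_drift_amp = 0,
         occlusion_rate = 0, mislabel_rate = 0),
    list(...))
  cfg <- do.call(synth_config, args)
  simulate_video(cfg, class, seed = seed)
}

# small feature matrix for clip-level tests
small_fm <- function(n_frames = 400, seed = 5) {
  set.seed(seed)
  vals <- matrix(stats::rnorm(36 * n_frames), 36, n_frames)
  ang <- matrix(stats::runif(10 * n_frames, 0, pi), 10, n_frames)
  feature_matrix(rbind(vals, ang), video_id = "fm1", fps = 25,
                 n_frames = n_frames)
}

# tiny trained-shape model object without running a full fit
fake_fit <- function(ctrl = gma_control(use_meta = FALSE), seed = 3) {
  set.seed(seed)
  params <- gmascreen:::nn_init(46, ctrl)
  structure(list(params = params, control = ctrl,
                 platt = structure(list(a = 1, c = 0, on_logit = TRUE),
                                   class = "platt_calibrator"),
                 history = data.frame(epoch = 1, train_loss = 1, val_loss = 1),
                 best_epoch = 1L, meta_scaling = list(age_mean = 0, age_sd = 1),
                 use_meta = ctrl$use_meta,
                 val_scores = data.frame(raw = numeric(0), y = integer(0)),
                 n_train = 0L),
            class = "gma_fit")
}
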