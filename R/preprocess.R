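#' Preprocessing configuration
#'
#' Parameters of the keypoint preprocessing pipeline, in pipeline order:
#' confidence filtering, quality control, global and pointwise elliptical
#' outlier removal, gap filling, rotation alignment, unit-length scaling and
#' framerate normalisation.
#'
#' @param confidence_min Prediction-confidence threshold; coordinates with
#'   confidence strictly below it are removed (default 0.2).
#' @param qc_min_labelled Minimum mean fraction of labelled body points per
#'   frame for a video to pass quality control (default 0.70; pass at
#'   exactly 0.70).
#' @param global_ellipse Semi-axes of the whole-body outlier ellipse in unit
#'   lengths, `c(proximal_distal, medial_lateral)` (default `c(3, 2)`).
#' @param pointwise_k SD multiplier for the per-point outlier ellipse
#'   (default 4).
#' @param pointwise_floor Minimum per-point ellipse semi-axis in unit lengths,
#'   guarding degenerate (still) points (default 0.05).
#' @param gap_linear_max Longest gap (frames) filled by linear interpolation;
#'   longer gaps use the iterative multivariate imputer (default 5).
#' @param target_frames Output frame count after resampling (default 4500,
#'   i.e. 3 minutes at 25 fps); `NULL` derives it from the native duration at
#'   `target_fps`.
#' @param target_fps Nominal output frame rate (default 25).
#' @param imputer_max_iter,imputer_tol Iteration cap and convergence
#'   tolerance (max absolute change, unit lengths) of the round-robin
#'   regression imputer.
#' @param center Translate each frame so mid-hip sits at the origin
#'   (default TRUE), making coordinates pose-relative.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(confidence_min = 0.2,
                              qc_min_labelled = 0.70,
                              global_ellipse = c(3, 2),
                              pointwise_k = 4,
                              pointwise_floor = 0.05,
                              gap_linear_max = 5L,
                              target_frames = 4500L,
                              target_fps = 25,
                              imputer_max_iter = 10L,
                              imputer_tol = 1e-3,
                              center = TRUE) {
  stopifnot(confidence_min >= 0, qc_min_labelled > 0, qc_min_labelled <= 1,
            all(global_ellipse > 0), pointwise_k > 0, gap_linear_max >= 1,
            target_fps > 0, imputer_max_iter >= 1, imputer_tol > 0)
  structure(as.list(environment()), class = "preprocess_config")
}

#' Remove low-confidence body points
#'
#' Coordinates whose prediction confidence is strictly below `confidence_min`
#' become missing; all other values are untouched.
#'
#' @param ts A [keypoint_ts()].
#' @param confidence_min Threshold (default 0.2).
#' @return A [keypoint_ts()] with low-confidence coordinates set to `NA`.
#' @export
filter_confidence <- function(ts, confidence_min = 0.2) {
  stopifnot(inherits(ts, "keypoint_ts"))
  drop <- !is.na(ts$confidence) & ts$confidence < confidence_min
  ts$x[drop] <- NA_real_
  ts$y[drop] <- NA_real_
  ts
}

#' Video-level labelling quality control
#'
#' Computes the mean over frames of the fraction of the 18 body points that
#' are labelled (non-missing), after confidence filtering. A video passes if
#' the fraction is at least `qc_min_labelled`.
#'
#' @param ts A [keypoint_ts()] (confidence-filtered).
#' @param qc_min_labelled Pass threshold (default 0.70; `>=` rule).
#' @return List with `pass` (logical) and `fraction`.
#' @export
qc_pass <- function(ts, qc_min_labelled = 0.70) {
  frac <- mean(rowMeans(!is.na(ts$x)))
  list(pass = frac >= qc_min_labelled, fraction = frac)
}

# vectorized torso frame over all frames: centres, axes and unit lengths;
# frames missing crown/shoulders/hips get valid = FALSE
.torso_all <- function(ts) {
  sh <- cbind((ts$x[, "left_shoulder"] + ts$x[, "right_shoulder"]) / 2,
              (ts$y[, "left_shoulder"] + ts$y[, "right_shoulder"]) / 2)
  hp <- cbind((ts$x[, "left_hip"] + ts$x[, "right_hip"]) / 2,
              (ts$y[, "left_hip"] + ts$y[, "right_hip"]) / 2)
  cr <- cbind(ts$x[, "crown"], ts$y[, "crown"])
  ctr <- (sh + hp) / 2
  pd <- sh - hp                              # mid-hip -> mid-shoulder
  pd_len <- sqrt(rowSums(pd^2))
  unit <- sqrt(rowSums((cr - hp)^2))
  valid <- !is.na(pd_len) & !is.na(unit) & pd_len > 0 & unit > 0
  pd_dir <- pd / ifelse(pd_len > 0, pd_len, NA_real_)
  ml_dir <- cbind(-pd_dir[, 2], pd_dir[, 1])  # perpendicular
  list(center = ctr, unit = unit, pd = pd_dir, ml = ml_dir,
       mid_sh = sh, mid_hip = hp, valid = valid)
}

#' Torso reference frame of a single frame
#'
#' Centre (mid-point of mid-shoulder and mid-hip), infant unit length
#' (crown-to-mid-hip distance) and the proximal-distal / medial-lateral unit
#' axes for one video frame.
#'
#' @param ts A [keypoint_ts()].
#' @param frame Frame index (1-based).
#' @return List with `center` (length-2), `unit_length`, `axes` (2 x 2 matrix,
#'   rows proximal-distal and medial-lateral).
#' @export
torso_frame <- function(ts, frame) {
  tf <- .torso_all(ts)
  if (!isTRUE(tf$valid[frame]))
    stop("torso frame is degenerate or incomputable at frame ", frame)
  list(center = tf$center[frame, ], unit_length = tf$unit[frame],
       axes = rbind(proximal_distal = tf$pd[frame, ],
                    medial_lateral = tf$ml[frame, ]))
}

#' Whole-body elliptical outlier removal
#'
#' Removes, frame by frame, body points lying outside an ellipse centred at
#' the torso centre with semi-axes of (by default) 3 unit lengths in the
#' proximal-distal direction and 2 unit lengths in the medial-lateral
#' direction. Frames whose torso frame cannot be computed are left untouched.
#'
#' @param ts A [keypoint_ts()].
#' @param cfg A [preprocess_config()].
#' @return A [keypoint_ts()] with out-of-envelope coordinates set to `NA`.
#' @export
remove_outliers_global <- function(ts, cfg = preprocess_config()) {
  tf <- .torso_all(ts)
  a <- cfg$global_ellipse[1]; b <- cfg$global_ellipse[2]
  for (j in seq_len(18)) {
    dx <- ts$x[, j] - tf$center[, 1]
    dy <- ts$y[, j] - tf$center[, 2]
    q_pd <- (dx * tf$pd[, 1] + dy * tf$pd[, 2]) / tf$unit
    q_ml <- (dx * tf$ml[, 1] + dy * tf$ml[, 2]) / tf$unit
    out <- tf$valid & !is.na(q_pd) & ((q_pd / a)^2 + (q_ml / b)^2 > 1)
    ts$x[out, j] <- NA_real_
    ts$y[out, j] <- NA_real_
  }
  ts
}

#' Per-point elliptical outlier removal
#'
#' For each body point, removes frames lying outside an ellipse centred at
#' the point's framewise median position (in torso coordinates, unit lengths)
#' with semi-axes `pointwise_k` robust standard deviations (1.4826 x MAD) in
#' the proximal-distal and medial-lateral directions, floored at
#' `pointwise_floor` unit lengths. Points observed in fewer than 10 frames
#' are skipped with a warning.
#'
#' @param ts A [keypoint_ts()].
#' @param cfg A [preprocess_config()].
#' @param dataset_stats Optional fixed statistics (as returned by
#'   [pointwise_stats()]) estimated over a whole dataset; when given, the
#'   stage is deterministic in them and exactly idempotent.
#' @return A [keypoint_ts()].
#' @export
remove_outliers_pointwise <- function(ts, cfg = preprocess_config(),
                                      dataset_stats = NULL) {
  tf <- .torso_all(ts)
  qpd <- qml <- matrix(NA_real_, ts$n_frames, 18)
  for (j in seq_len(18)) {
    dx <- ts$x[, j] - tf$center[, 1]
    dy <- ts$y[, j] - tf$center[, 2]
    qpd[, j] <- ifelse(tf$valid, (dx * tf$pd[, 1] + dy * tf$pd[, 2]) / tf$unit,
                       NA_real_)
    qml[, j] <- ifelse(tf$valid, (dx * tf$ml[, 1] + dy * tf$ml[, 2]) / tf$unit,
                       NA_real_)
  }
  st <- if (is.null(dataset_stats)) .pointwise_stats_q(qpd, qml) else dataset_stats
  for (j in seq_len(18)) {
    obs <- !is.na(qpd[, j])
    if (sum(obs) < 10) {
      .log("pointwise outlier stage skipped for ", body_points()[j],
           " (", sum(obs), " labelled frames)")
      next
    }
    apd <- max(cfg$pointwise_k * st$sd_pd[j], cfg$pointwise_floor)
    aml <- max(cfg$pointwise_k * st$sd_ml[j], cfg$pointwise_floor)
    out <- obs & (((qpd[, j] - st$med_pd[j]) / apd)^2 +
                    ((qml[, j] - st$med_ml[j]) / aml)^2 > 1)
    ts$x[out, j] <- NA_real_
    ts$y[out, j] <- NA_real_
  }
  ts
}

.pointwise_stats_q <- function(qpd, qml) {
  rsd <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(0)
    stats::mad(v)
  }
  list(med_pd = apply(qpd, 2, stats::median, na.rm = TRUE),
       med_ml = apply(qml, 2, stats::median, na.rm = TRUE),
       sd_pd = apply(qpd, 2, rsd),
       sd_ml = apply(qml, 2, rsd))
}

#' Dataset-level per-point position statistics
#'
#' Median position and robust SD of each body point in torso coordinates
#' (unit lengths), pooled over a list of videos; feed the result to
#' [remove_outliers_pointwise()] to mirror scaling the per-point envelopes by
#' variance observed across a complete dataset.
#'
#' @param ts_list List of [keypoint_ts()].
#' @return List with `med_pd`, `med_ml`, `sd_pd`, `sd_ml` (each length 18).
#' @export
pointwise_stats <- function(ts_list) {
  qs <- lapply(ts_list, function(ts) {
    tf <- .torso_all(ts)
    qpd <- qml <- matrix(NA_real_, ts$n_frames, 18)
    for (j in seq_len(18)) {
      dx <- ts$x[, j] - tf$center[, 1]
      dy <- ts$y[, j] - tf$center[, 2]
      qpd[, j] <- ifelse(tf$valid,
                         (dx * tf$pd[, 1] + dy * tf$pd[, 2]) / tf$unit, NA)
      qml[, j] <- ifelse(tf$valid,
                         (dx * tf$ml[, 1] + dy * tf$ml[, 2]) / tf$unit, NA)
    }
    list(qpd = qpd, qml = qml)
  })
  .pointwise_stats_q(do.call(rbind, lapply(qs, `[[`, "qpd")),
                     do.call(rbind, lapply(qs, `[[`, "qml")))
}

#' Fill gaps in a keypoint timeseries
#'
#' Interior gaps of `gap_linear_max` frames or fewer are filled by linear
#' interpolation between the flanking observations. Longer gaps (and leading
#' or trailing gaps) are first initialised by nearest-observation
#' interpolation and then refined by a round-robin iterative multivariate
#' imputer: each affected coordinate channel is regressed (ordinary least
#' squares with intercept) on the other 35 channels over its observed frames
#' and its missing frames replaced by the prediction, repeating until the
#' largest change falls below `imputer_tol` or `imputer_max_iter` passes.
#' Observed values are never altered.
#'
#' @param ts A [keypoint_ts()].
#' @param cfg A [preprocess_config()].
#' @return A [keypoint_ts()] with no missing coordinates.
#' @export
fill_gaps <- function(ts, cfg = preprocess_config()) {
  n <- ts$n_frames
  chan <- cbind(ts$x, ts$y)                  # n x 36
  colnames(chan) <- c(paste0(body_points(), "_x"), paste0(body_points(), "_y"))
  obs <- !is.na(chan)
  none <- which(colSums(obs) == 0)
  if (length(none))
    stop("no observed frames for channel(s): ",
         paste(colnames(chan)[none], collapse = ", "))

  long_mask <- matrix(FALSE, n, ncol(chan))
  for (j in seq_len(ncol(chan))) {
    miss <- is.na(chan[, j])
    if (!any(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      run <- starts[k]:ends[k]
      interior <- starts[k] > 1 && ends[k] < n
      if (interior && r$lengths[k] <= cfg$gap_linear_max) {
        x0 <- starts[k] - 1; x1 <- ends[k] + 1
        chan[run, j] <- chan[x0, j] +
          (chan[x1, j] - chan[x0, j]) * (run - x0) / (x1 - x0)
      } else {
        long_mask[run, j] <- TRUE
      }
    }
    # initialise remaining gaps: linear inside, nearest at the edges
    if (anyNA(chan[, j])) {
      idx <- which(!is.na(chan[, j]))
      chan[, j] <- stats::approx(idx, chan[idx, j], xout = seq_len(n),
                                 rule = 2)$y
    }
  }

  targets <- which(colSums(long_mask) > 0)
  if (length(targets)) {
    for (it in seq_len(cfg$imputer_max_iter)) {
      delta <- 0
      for (j in targets) {
        rows_fit <- obs[, j]
        X <- cbind(1, chan[, -j, drop = FALSE])
        fit <- stats::lm.fit(X[rows_fit, , drop = FALSE], chan[rows_fit, j])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        pred <- X[long_mask[, j], , drop = FALSE] %*% beta
        delta <- max(delta, max(abs(pred - chan[long_mask[, j], j])))
        chan[long_mask[, j], j] <- pred
      }
      if (delta < cfg$imputer_tol) break
    }
  }

  ts$x <- chan[, 1:18, drop = FALSE]
  ts$y <- chan[, 19:36, drop = FALSE]
  colnames(ts$x) <- colnames(ts$y) <- body_points()
  ts
}

#' Frame-by-frame rotation alignment
#'
#' Rotates every frame about its torso centre so the body midline
#' (mid-shoulder to mid-hip) is vertical, with the mid-hip below the
#' mid-shoulder in image coordinates. Pairwise inter-point distances are
#' preserved. This removes angular camera motion relative to the infant.
#'
#' @param ts A gap-filled [keypoint_ts()].
#' @return A [keypoint_ts()] in body-aligned coordinates.
#' @export
align_rotation <- function(ts) {
  tf <- .torso_all(ts)
  d <- tf$mid_hip - tf$mid_sh
  len <- sqrt(rowSums(d^2))
  if (any(!is.finite(len)) || any(len == 0))
    stop("degenerate midline (zero length) at frame ",
         which(!is.finite(len) | len == 0)[1])
  co <- d[, 2] / len; si <- d[, 1] / len      # maps midline onto +y (down)
  cx <- tf$center[, 1]; cy <- tf$center[, 2]
  for (j in seq_len(18)) {
    dx <- ts$x[, j] - cx; dy <- ts$y[, j] - cy
    ts$x[, j] <- cx + co * dx - si * dy
    ts$y[, j] <- cy + si * dx + co * dy
  }
  ts
}

#' Scale to infant unit length and centre on the mid-hip
#'
#' Divides all coordinates by the per-video median crown-to-mid-hip distance
#' (the infant unit length) and, when `center` is enabled, translates each
#' frame so the mid-hip lies at the origin, making coordinates pose-relative
#' and invariant to camera zoom and translation.
#'
#' @param ts A rotation-aligned [keypoint_ts()].
#' @param center Translate per-frame mid-hip to the origin (default TRUE).
#' @return A [keypoint_ts()] in unit-length coordinates.
#' @export
scale_and_center <- function(ts, center = TRUE) {
  tf <- .torso_all(ts)
  u <- stats::median(tf$unit, na.rm = TRUE)
  if (!is.finite(u) || u <= 0) stop("zero or undefined infant unit length")
  if (center) {
    ts$x <- (ts$x - tf$mid_hip[, 1]) / u
    ts$y <- (ts$y - tf$mid_hip[, 2]) / u
  } else {
    ts$x <- ts$x / u
    ts$y <- ts$y / u
  }
  ts
}

#' Framerate normalisation by cubic interpolation
#'
#' Resamples every coordinate channel from its native timestamps onto a
#' uniform grid of `target_frames` timepoints spanning the video duration
#' (nominally 4500 timepoints / 25 fps for a 3-minute video) using cubic
#' spline interpolation.
#'
#' @param ts A complete (gap-free) [keypoint_ts()].
#' @param cfg A [preprocess_config()].
#' @return A [keypoint_ts()] with `target_frames` frames and the nominal fps.
#' @export
resample_frames <- function(ts, cfg = preprocess_config()) {
  n <- ts$n_frames
  if (n < 4) stop("cubic interpolation requires at least 4 frames, got ", n)
  if (anyNA(ts$x) || anyNA(ts$y))
    stop("resampling requires a gap-free timeseries; run fill_gaps() first")
  t_in <- (seq_len(n) - 1) / ts$fps
  n_out <- if (is.null(cfg$target_frames))
    round(t_in[n] * cfg$target_fps) else cfg$target_frames
  t_out <- seq(0, t_in[n], length.out = n_out)
  res <- function(v) stats::spline(t_in, v, xout = t_out, method = "fmm")$y
  x <- apply(ts$x, 2, res); y <- apply(ts$y, 2, res)
  keypoint_ts(ts$video_id, cfg$target_fps, x, y,
              matrix(1, n_out, 18))
}

#' Two-dimensional joint angles
#'
#' Interior angle (radians, in `[0, pi]`) at each of 10 joints, computed as
#' the arccosine of the normalised dot product of the joint's two defining
#' segments: shoulder (shoulder to ipsilateral hip / to elbow), elbow (to
#' shoulder / to wrist), hip (to ipsilateral shoulder / to knee), knee (to
#' hip / to heel) and ankle (heel to knee / to big toe). A zero-length
#' segment yields `pi` with a warning.
#'
#' @param x,y Gap-free coordinate matrices `n x 18` in [body_points()] column
#'   order.
#' @return Numeric matrix `n x 10` (columns: left/right shoulder, elbow, hip,
#'   knee, ankle).
#' @export
joint_angles <- function(x, y) {
  ang <- function(vx1, vy1, vx2, vy2) {
    n1 <- sqrt(vx1^2 + vy1^2); n2 <- sqrt(vx2^2 + vy2^2)
    degen <- n1 == 0 | n2 == 0
    if (any(degen)) warning("zero-length segment in joint angle; set to pi")
    cosang <- (vx1 * vx2 + vy1 * vy2) / (n1 * n2)
    out <- acos(pmin(1, pmax(-1, cosang)))
    out[degen] <- pi
    out
  }
  seg <- function(from, to) list(x = x[, to] - x[, from], y = y[, to] - y[, from])
  out <- matrix(NA_real_, nrow(x), 10)
  k <- 0
  for (side in c("left_", "right_")) {
    k <- k + 1
    a <- seg(paste0(side, "shoulder"), paste0(side, "hip"))
    b <- seg(paste0(side, "shoulder"), paste0(side, "elbow"))
    out[, k] <- ang(a$x, a$y, b$x, b$y)
  }
  for (side in c("left_", "right_")) {
    k <- k + 1
    a <- seg(paste0(side, "elbow"), paste0(side, "shoulder"))
    b <- seg(paste0(side, "elbow"), paste0(side, "wrist"))
    out[, k] <- ang(a$x, a$y, b$x, b$y)
  }
  for (side in c("left_", "right_")) {
    k <- k + 1
    a <- seg(paste0(side, "hip"), paste0(side, "shoulder"))
    b <- seg(paste0(side, "hip"), paste0(side, "knee"))
    out[, k] <- ang(a$x, a$y, b$x, b$y)
  }
  for (side in c("left_", "right_")) {
    k <- k + 1
    a <- seg(paste0(side, "knee"), paste0(side, "hip"))
    b <- seg(paste0(side, "knee"), paste0(side, "heel"))
    out[, k] <- ang(a$x, a$y, b$x, b$y)
  }
  for (side in c("left_", "right_")) {
    k <- k + 1
    a <- seg(paste0(side, "heel"), paste0(side, "knee"))
    b <- seg(paste0(side, "heel"), paste0(side, "bigtoe"))
    out[, k] <- ang(a$x, a$y, b$x, b$y)
  }
  # column order: L/R per joint, joints in shoulder/elbow/hip/knee/ankle order
  colnames(out) <- feature_row_names()[37:46]
  out
}

#' Assemble the feature matrix
#'
#' Stacks the 36 coordinate channels (x before y, in [body_points()] order)
#' and the 10 joint angles of a fully preprocessed timeseries into the
#' `46 x n_frames` feature-by-frame matrix consumed by the classifier.
#'
#' @param ts A preprocessed, resampled [keypoint_ts()].
#' @return A [feature_matrix()].
#' @export
extract_features <- function(ts) {
  if (anyNA(ts$x) || anyNA(ts$y))
    stop("feature extraction requires a gap-free timeseries")
  n <- ts$n_frames
  coords <- matrix(NA_real_, 36, n)
  coords[seq(1, 35, by = 2), ] <- t(ts$x)
  coords[seq(2, 36, by = 2), ] <- t(ts$y)
  angles <- t(joint_angles(ts$x, ts$y))
  feature_matrix(rbind(coords, angles), video_id = ts$video_id,
                 fps = ts$fps, n_frames = n)
}

#' Run the full preprocessing pipeline on one video
#'
#' Applies, in order: confidence filtering, quality control, whole-body and
#' per-point elliptical outlier removal, gap filling, rotation alignment,
#' unit-length scaling/centring, framerate normalisation and feature
#' extraction.
#'
#' @param ts A raw [keypoint_ts()].
#' @param cfg A [preprocess_config()].
#' @param dataset_stats Optional pooled statistics for the pointwise outlier
#'   stage (see [pointwise_stats()]).
#' @param enforce_qc Error on videos failing quality control (default TRUE);
#'   otherwise a warning is emitted and processing continues.
#' @return A [feature_matrix()] with attribute `qc` (list: fraction, pass,
#'   n_removed_confidence, n_removed_global, n_removed_pointwise).
#' @export
preprocess_video <- function(ts, cfg = preprocess_config(),
                             dataset_stats = NULL, enforce_qc = TRUE) {
  stopifnot(inherits(ts, "keypoint_ts"), inherits(cfg, "preprocess_config"))
  n_na0 <- sum(is.na(ts$x))
  ts <- filter_confidence(ts, cfg$confidence_min)
  n_na1 <- sum(is.na(ts$x))
  qc <- qc_pass(ts, cfg$qc_min_labelled)
  if (!qc$pass) {
    msg <- sprintf("video %s fails quality control: %.1f%% labelled (< %.0f%%)",
                   ts$video_id, 100 * qc$fraction, 100 * cfg$qc_min_labelled)
    if (enforce_qc) stop(msg) else warning(msg)
  }
  ts <- remove_outliers_global(ts, cfg)
  n_na2 <- sum(is.na(ts$x))
  ts <- remove_outliers_pointwise(ts, cfg, dataset_stats)
  n_na3 <- sum(is.na(ts$x))
  ts <- fill_gaps(ts, cfg)
  ts <- align_rotation(ts)
  ts <- scale_and_center(ts, cfg$center)
  ts <- resample_frames(ts, cfg)
  fm <- extract_features(ts)
  attr(fm, "qc") <- list(fraction = qc$fraction, pass = qc$pass,
                         n_removed_confidence = n_na1 - n_na0,
                         n_removed_global = n_na2 - n_na1,
                         n_removed_pointwise = n_na3 - n_na2)
  fm
}
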