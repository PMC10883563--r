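#' Synthetic infant movement configuration
#'
#' Parameters of the synthetic supine-infant keypoint simulator. The
#' simulator emulates the statistical structure of smartphone-acquired infant
#' videos processed by a pose-estimation model: ~3-minute recordings at 15-31
#' frames per second, hand-held camera rotation and drift, per-point occlusion
#' episodes with low prediction confidence, occasional high-confidence
#' mislabelling outliers, and class-dependent small-amplitude "fidgety"
#' movement superimposed on slow gross limb movements.
#'
#' Normal-class videos carry band-limited fidgety oscillations (default
#' 0.5-3 Hz, amplitude `fidgety_amp` infant unit lengths) at all limb points,
#' strongest in the lower body; abnormal-class videos have the fidgety
#' component either suppressed (x0.1, "absent") or exaggerated (x3,
#' "abnormal"), chosen at random per video, emulating the pooling of absent
#' and abnormal ratings into one screening-positive class.
#'
#' @param n_videos Number of videos to simulate.
#' @param p_abnormal Proportion of abnormal/absent-class videos (default
#'   76/484, the observed screening prevalence).
#' @param duration_s Video duration in seconds (default 180).
#' @param fps_range Integer range of native frame rates (default 15-31).
#' @param resolution Video width x height in pixels.
#' @param scale_px Infant crown-to-mid-hip distance in pixels.
#' @param camera_rot_amp Peak camera rotation in degrees (default 15).
#' @param camera_drift_amp Peak camera translation drift in pixels.
#' @param occlusion_rate Expected occlusion episodes per point per minute.
#' @param occlusion_len_range Occlusion episode length range in frames.
#' @param mislabel_rate Fraction of frames per point displaced by a
#'   high-confidence outlier jump (>= 1 unit length).
#' @param fidgety_amp Fidgety movement amplitude in unit lengths.
#' @param fidgety_band Fidgety frequency band in Hz.
#' @param gross_move_amp Slow gross movement amplitude in unit lengths.
#' @param two_video_fraction Fraction of infants contributing two videos when
#'   grouping is enabled in [generate_dataset()].
#' @param seed Integer seed stored with the config (used by
#'   [generate_dataset()] when no explicit seed is given).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_videos = 100,
                         p_abnormal = 76 / 484,
                         duration_s = 180,
                         fps_range = c(15L, 31L),
                         resolution = c(480L, 360L),
                         scale_px = 0.35 * min(resolution),
                         camera_rot_amp = 15,
                         camera_drift_amp = 20,
                         occlusion_rate = 0.5,
                         occlusion_len_range = c(3L, 40L),
                         mislabel_rate = 0.002,
                         fidgety_amp = 0.03,
                         fidgety_band = c(0.5, 3),
                         gross_move_amp = 0.15,
                         two_video_fraction = 160 / 341,
                         seed = 1L) {
  stopifnot(p_abnormal >= 0, p_abnormal <= 1,
            fps_range[1] >= 15, fps_range[2] <= 31,
            duration_s > 0, scale_px > 0,
            mislabel_rate >= 0, mislabel_rate <= 1,
            two_video_fraction >= 0, two_video_fraction <= 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Base supine infant skeleton
#'
#' Returns an anatomically plausible supine pose for the 18 canonical body
#' points, in image coordinates (y down), centred so that the crown-to-mid-hip
#' segment is vertical with length `scale_px` pixels and left/right point
#' pairs mirrored about the midline.
#'
#' @param scale_px Crown-to-mid-hip distance in pixels (> 0).
#' @return A `2 x 18` matrix (rows x, y; columns in [body_points()] order),
#'   in units of pixels, with the crown at the origin.
#' @export
make_skeleton <- function(scale_px) {
  stopifnot(scale_px > 0)
  # (x, y) in crown-to-mid-hip units; "left_" points on +x
  base <- c(
    crown = c(0, 0), chin = c(0, 0.22),
    left_eye = c(0.08, 0.10), right_eye = c(-0.08, 0.10),
    left_shoulder = c(0.25, 0.35), right_shoulder = c(-0.25, 0.35),
    left_elbow = c(0.45, 0.55), right_elbow = c(-0.45, 0.55),
    left_wrist = c(0.50, 0.30), right_wrist = c(-0.50, 0.30),
    left_hip = c(0.16, 1.00), right_hip = c(-0.16, 1.00),
    left_knee = c(0.30, 1.30), right_knee = c(-0.30, 1.30),
    left_heel = c(0.28, 1.62), right_heel = c(-0.28, 1.62),
    left_bigtoe = c(0.35, 1.75), right_bigtoe = c(-0.35, 1.75))
  m <- matrix(base, nrow = 2, dimnames = list(c("x", "y"), body_points()))
  m * scale_px
}

# per-point movement weights (unit-length scale): fidgety dominates the lower
# body, echoing the greater discriminative load carried by knees and ankles
.w_fidgety <- function() {
  w <- stats::setNames(rep(0.1, 18), body_points())
  w[c("left_knee", "right_knee", "left_heel", "right_heel",
      "left_bigtoe", "right_bigtoe")] <- 1.0
  w[c("left_wrist", "right_wrist")] <- 0.8
  w[c("left_elbow", "right_elbow")] <- 0.6
  w[c("left_hip", "right_hip", "left_shoulder", "right_shoulder")] <- 0.0
  w
}

.w_gross <- function() {
  w <- stats::setNames(rep(0.15, 18), body_points())
  w[c("left_wrist", "right_wrist", "left_elbow", "right_elbow",
      "left_knee", "right_knee", "left_heel", "right_heel",
      "left_bigtoe", "right_bigtoe")] <- 1.0
  w[c("left_hip", "right_hip", "left_shoulder", "right_shoulder")] <- 0.0
  w
}

#' Simulate a single labelled synthetic video
#'
#' Generates one supine-infant keypoint timeseries according to a
#' [synth_config()]. The trunk (shoulders and hips) translates rigidly with
#' slow noise; limbs and head add independent slow gross movement, and limbs
#' carry the band-limited fidgety component whose amplitude encodes the class.
#' A slow random-walk camera rotation and translation is applied to all
#' points, and the applied camera trajectory is retained as ground truth so
#' the rotation-alignment stage can be oracle-tested. Occluded frames draw
#' prediction confidence from U(0, 0.2) (below the removal threshold);
#' visible frames from U(0.7, 1) when occlusion modelling is active and 1
#' otherwise. Mislabelled frames are displaced by 1.2-2.5 unit lengths at
#' full confidence.
#'
#' @param cfg A [synth_config()].
#' @param class 0 = normal GMs, 1 = abnormal/absent.
#' @param video_id Identifier for the video.
#' @param seed Optional integer seed (local to this call).
#' @return A list of class `synthetic_video` with elements `ts`
#'   ([keypoint_ts()]), `meta` (age_weeks, cohort, gms_label, gms_binary) and
#'   `truth` (class, fidgety multiplier, per-frame camera angle in radians,
#'   2 x n drift in pixels).
#' @export
simulate_video <- function(cfg, class, video_id = "video_1", seed = NULL) {
  stopifnot(inherits(cfg, "synth_config"), class %in% c(0, 1))
  with_seed(seed, {
    fps <- sample(seq(cfg$fps_range[1], cfg$fps_range[2]), 1)
    n <- round(cfg$duration_s * fps)
    bp <- body_points()
    base <- make_skeleton(cfg$scale_px)           # 2 x 18, pixels
    u <- cfg$scale_px                             # pixels per unit length

    fid_mult <- 1
    if (class == 1) fid_mult <- sample(c(0.1, 3), 1)

    # trunk rigid translation shared by shoulders + hips (and weakly by head)
    trunk <- rbind(slow_noise(n, fps, 0.3, 0.05 * u),
                   slow_noise(n, fps, 0.3, 0.05 * u))
    xs <- matrix(0, n, 18, dimnames = list(NULL, bp))
    ys <- matrix(0, n, 18, dimnames = list(NULL, bp))
    wf <- .w_fidgety(); wg <- .w_gross()
    trunk_pts <- c("left_shoulder", "right_shoulder", "left_hip", "right_hip")
    for (j in seq_along(bp)) {
      p <- bp[j]
      gx <- slow_noise(n, fps, 0.4, cfg$gross_move_amp * wg[p] * u)
      gy <- slow_noise(n, fps, 0.4, cfg$gross_move_amp * wg[p] * u)
      fx <- band_noise(n, fps, cfg$fidgety_band[1], cfg$fidgety_band[2],
                       cfg$fidgety_amp * wf[p] * u) * fid_mult
      fy <- band_noise(n, fps, cfg$fidgety_band[1], cfg$fidgety_band[2],
                       cfg$fidgety_amp * wf[p] * u) * fid_mult
      tr <- if (p %in% trunk_pts) 1 else if (j <= 4) 0.5 else 0
      xs[, j] <- base["x", j] + gx + fx + tr * trunk[1, ]
      ys[, j] <- base["y", j] + gy + fy + tr * trunk[2, ]
    }

    # place infant at image centre
    ctr <- cfg$resolution / 2
    xs <- xs + ctr[1]
    ys <- ys + ctr[2] - cfg$scale_px * 0.85      # roughly centre the body

    # camera: slow rotation about the image centre plus translation drift
    smooth01 <- function(amp) {
      if (amp == 0) return(numeric(n))
      s <- slow_noise(n, fps, 0.15, 1)
      m <- max(abs(s))
      if (m < .Machine$double.eps) numeric(n) else s / m * amp
    }
    theta <- smooth01(cfg$camera_rot_amp * pi / 180)
    drift <- rbind(smooth01(cfg$camera_drift_amp),
                   smooth01(cfg$camera_drift_amp))
    ct <- cos(theta); st <- sin(theta)
    dx <- xs - ctr[1]; dy <- ys - ctr[2]
    xs_obs <- ctr[1] + ct * dx - st * dy + drift[1, ]
    ys_obs <- ctr[2] + st * dx + ct * dy + drift[2, ]

    # confidence: occlusion episodes push confidence under the 0.2 threshold
    if (cfg$occlusion_rate > 0) {
      conf <- matrix(stats::runif(n * 18, 0.7, 1), n, 18)
      n_ep <- stats::rpois(18, cfg$occlusion_rate * cfg$duration_s / 60)
      for (j in which(n_ep > 0)) {
        for (k in seq_len(n_ep[j])) {
          len <- sample(seq(cfg$occlusion_len_range[1],
                            cfg$occlusion_len_range[2]), 1)
          s0 <- sample.int(max(n - len, 1), 1)
          idx <- s0:min(s0 + len - 1, n)
          conf[idx, j] <- stats::runif(length(idx), 0, 0.2)
        }
      }
    } else {
      conf <- matrix(1, n, 18)
    }

    # high-confidence mislabelling outliers (>= 1 unit length displacement)
    if (cfg$mislabel_rate > 0) {
      hits <- which(matrix(stats::runif(n * 18), n, 18) < cfg$mislabel_rate)
      if (length(hits)) {
        ang <- stats::runif(length(hits), 0, 2 * pi)
        mag <- stats::runif(length(hits), 1.2, 2.5) * u
        xs_obs[hits] <- xs_obs[hits] + mag * cos(ang)
        ys_obs[hits] <- ys_obs[hits] + mag * sin(ang)
        conf[hits] <- pmax(conf[hits], 0.9)
      }
    }

    # preterm birth enriched in the abnormal class (screening cohorts skew
    # heavily preterm among abnormal ratings)
    cohort_p <- if (class == 1) 0.85 else 0.30
    cohort <- if (stats::runif(1) < cohort_p) "preterm" else "term"
    gms_label <- if (class == 0) "normal" else if (fid_mult < 1) "absent" else "abnormal"
    meta <- list(age_weeks = stats::runif(1, 12, 18), cohort = cohort,
                 resolution = cfg$resolution,
                 gms_label = gms_label, gms_binary = as.integer(class))
    structure(
      list(ts = keypoint_ts(video_id, fps, xs_obs, ys_obs, conf),
           meta = meta,
           truth = list(class = class, fid_mult = fid_mult,
                        cam_theta = theta, cam_drift = drift)),
      class = "synthetic_video")
  })
}

#' Generate a labelled synthetic dataset
#'
#' Simulates `cfg$n_videos` videos with class labels drawn at probability
#' `cfg$p_abnormal`. With `group = TRUE`, a fraction of infants (default
#' matching the source cohort, where 160/341 infants contributed two videos)
#' contribute two videos sharing one infant id and one class, enabling
#' grouped cross-validation tests.
#'
#' @param cfg A [synth_config()].
#' @param group Logical; give some infants two videos (default TRUE).
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return A list with `videos` (list of `synthetic_video`) and `labels`
#'   (data.frame: video_id, infant_id, gms_label, gms_binary, cohort,
#'   age_weeks, fps).
#' @export
generate_dataset <- function(cfg, group = TRUE, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(seed, {
    n <- cfg$n_videos
    videos <- vector("list", n)
    rows <- vector("list", n)
    i <- 0L; infant <- 0L
    while (i < n) {
      infant <- infant + 1L
      k <- if (group && stats::runif(1) < cfg$two_video_fraction) 2L else 1L
      k <- min(k, n - i)
      cls <- stats::rbinom(1, 1, cfg$p_abnormal)
      for (v in seq_len(k)) {
        i <- i + 1L
        vid <- sprintf("vid%04d", i)
        sv <- simulate_video(cfg, cls, video_id = vid)
        videos[[i]] <- sv
        rows[[i]] <- data.frame(
          video_id = vid, infant_id = sprintf("inf%04d", infant),
          gms_label = sv$meta$gms_label, gms_binary = cls,
          cohort = sv$meta$cohort, age_weeks = sv$meta$age_weeks,
          fps = sv$ts$fps, stringsAsFactors = FALSE)
      }
    }
    labels <- if (n == 0) data.frame(
      video_id = character(0), infant_id = character(0),
      gms_label = character(0), gms_binary = integer(0),
      cohort = character(0), age_weeks = numeric(0), fps = numeric(0),
      stringsAsFactors = FALSE) else do.call(rbind, rows)
    list(videos = videos, labels = labels)
  })
}
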