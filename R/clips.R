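#' Sliding-window clip extraction
#'
#' Splits a feature matrix into overlapping clips of `t` frames with the
#' given stride: starts 0, stride, 2*stride, ...; the clip count is
#' `floor((n_frames - t) / stride) + 1`. A standard 4500-frame video yields
#' 547 clips at the defaults (t = 128, stride = 8), roughly 5-second windows
#' at 25 fps.
#'
#' @param fm A [feature_matrix()] (or bare `46 x n` matrix).
#' @param t Clip length in frames (default 128).
#' @param stride Stride between clip starts (default 8).
#' @return List of clips; each clip is a `t x 46` matrix (time by feature)
#'   with attribute `start` (0-based start frame).
#' @export
make_clips <- function(fm, t = 128L, stride = 8L) {
  vals <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  n <- ncol(vals)
  if (n < t) stop("video has ", n, " frames; clips need at least ", t)
  starts <- seq(0L, n - t, by = stride)
  lapply(starts, function(s) {
    clip <- t(vals[, (s + 1):(s + t), drop = FALSE])
    attr(clip, "start") <- s
    clip
  })
}

#' Random clip sampling for training
#'
#' Draws `s` clips with uniformly random start indices (fresh each call);
#' the per-epoch training regime samples `s = 1` clip per video.
#'
#' @inheritParams make_clips
#' @param s Number of clips to draw (default 1).
#' @return List of `s` clips as in [make_clips()].
#' @export
sample_training_clips <- function(fm, t = 128L, stride = 8L, s = 1L) {
  vals <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  n <- ncol(vals)
  if (n < t) stop("video has ", n, " frames; clips need at least ", t)
  starts <- sample.int(n - t + 1L, s, replace = TRUE) - 1L
  lapply(starts, function(st) {
    clip <- t(vals[, (st + 1):(st + t), drop = FALSE])
    attr(clip, "start") <- st
    clip
  })
}

#' Augmentation configuration
#'
#' @param knots Integer range of random spline knot counts (default 3-15).
#' @param curve_mean,curve_sigma Normal distribution of knot values
#'   (defaults 1.0 and 1.0).
#' @param apply_magnitude,apply_warp Enable magnitude scaling / time warping.
#' @param warp_floor Lower clamp on the warp curve keeping the time map
#'   strictly increasing (default 0.1).
#' @param per_feature Draw an independent curve per feature instead of one
#'   shared curve (default FALSE, preserving inter-limb coordination).
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(knots = c(3L, 15L), curve_mean = 1.0,
                           curve_sigma = 1.0, apply_magnitude = TRUE,
                           apply_warp = TRUE, warp_floor = 0.1,
                           per_feature = FALSE) {
  stopifnot(knots[1] >= 2, knots[2] >= knots[1], curve_sigma >= 0,
            warp_floor > 0)
  structure(as.list(environment()), class = "augment_config")
}

#' Random smooth curve for augmentation
#'
#' A cubic spline through `k` knots placed uniformly across the clip length
#' with values drawn from N(curve_mean, curve_sigma^2), where
#' `k ~ U{knots[1]..knots[2]}`; evaluated at `t` points. With
#' `curve_sigma = 0` the curve is identically `curve_mean`.
#'
#' @param t Curve length (frames).
#' @param cfg An [augment_config()].
#' @return Numeric vector of length `t`.
#' @export
random_curve <- function(t, cfg = augment_config()) {
  stopifnot(t >= 2)
  k <- if (cfg$knots[2] > cfg$knots[1])
    sample(seq(cfg$knots[1], cfg$knots[2]), 1) else cfg$knots[1]
  xk <- seq(0, t - 1, length.out = k)
  yk <- stats::rnorm(k, cfg$curve_mean, cfg$curve_sigma)
  stats::spline(xk, yk, xout = seq_len(t) - 1, method = "fmm")$y
}

#' Smooth magnitude scaling of a clip
#'
#' Multiplies every feature timeseries in the clip element-wise with a smooth
#' curve along time. Columns listed in `angle_cols` (the joint-angle rows
#' during training) are instead scaled about pi/2 — deviations from a neutral
#' posture are scaled, not the absolute angle — and clipped back to
#' `[0, pi]`.
#'
#' @param clip `t x p` clip matrix.
#' @param curve Length-`t` curve (recycled across features), or a `t x p`
#'   matrix of per-feature curves.
#' @param angle_cols Column indices treated as angles (default none; the
#'   training chain passes 37:46).
#' @return Scaled clip of the same shape (attributes preserved).
#' @export
magnitude_scale <- function(clip, curve, angle_cols = integer(0)) {
  t_len <- nrow(clip)
  if (is.matrix(curve)) {
    if (!all(dim(curve) == dim(clip))) stop("curve/clip dimension mismatch")
  } else {
    if (length(curve) != t_len)
      stop("curve length ", length(curve), " does not match clip length ", t_len)
  }
  cmat <- if (is.matrix(curve)) curve else matrix(curve, t_len, ncol(clip))
  out <- clip * cmat
  if (length(angle_cols)) {
    ac <- angle_cols
    out[, ac] <- pmin(pi, pmax(0, (clip[, ac] - pi / 2) * cmat[, ac] + pi / 2))
  }
  attributes(out) <- attributes(clip)
  out
}

#' Smooth time warping of a clip
#'
#' The (positive) warp curve's cumulative sum defines a distorted time grid,
#' rescaled to `[0, t - 1]`; the clip is re-interpolated from the distorted
#' timestamps back onto the uniform grid with shape-preserving cubic
#' interpolation, so the warp map is strictly increasing, endpoints are
#' preserved and monotone channels stay monotone.
#'
#' @param clip `t x p` clip matrix.
#' @param curve Length-`t` positive curve (floored at `warp_floor`).
#' @param warp_floor Lower clamp applied to the curve (default 0.1).
#' @return Warped clip of the same shape (attributes preserved).
#' @export
time_warp <- function(clip, curve, warp_floor = 0.1) {
  t_len <- nrow(clip)
  if (length(curve) != t_len)
    stop("curve length ", length(curve), " does not match clip length ", t_len)
  if (any(!is.finite(curve))) stop("non-finite warp curve")
  w <- cumsum(pmax(curve, warp_floor))
  w <- (w - w[1]) / (w[t_len] - w[1]) * (t_len - 1)
  out <- .pchip_cols(w, clip, seq_len(t_len) - 1)
  attributes(out) <- attributes(clip)
  out
}

# shape-preserving (Fritsch-Carlson) piecewise-cubic interpolation of every
# column of Y from the shared strictly-increasing grid x onto query points q;
# vectorized across columns (the warp grid is shared by all features)
.pchip_cols <- function(x, Y, q) {
  n <- length(x)
  h <- diff(x)                                   # n-1
  Del <- (Y[-1, , drop = FALSE] - Y[-n, , drop = FALSE]) / h
  m <- rbind(Del, Del[n - 1, ])                  # n rows; interior replaced
  if (n > 2) {
    d0 <- Del[-(n - 1), , drop = FALSE]          # Del_{i-1} for i = 2..n-1
    d1 <- Del[-1, , drop = FALSE]                # Del_i
    h0 <- h[-(n - 1)]; h1 <- h[-1]
    wsum <- (2 * h1 + h0) / d0 + (h1 + 2 * h0) / d1
    mi <- 3 * (h0 + h1) / wsum
    mi[d0 * d1 <= 0 | !is.finite(mi)] <- 0
    m[2:(n - 1), ] <- mi
  }
  kk <- pmin(pmax(findInterval(q, x), 1L), n - 1L)
  th <- (q - x[kk]) / h[kk]
  h00 <- (1 + 2 * th) * (1 - th)^2
  h10 <- th * (1 - th)^2
  h01 <- th^2 * (3 - 2 * th)
  h11 <- th^2 * (th - 1)
  Y[kk, , drop = FALSE] * h00 +
    m[kk, , drop = FALSE] * (h10 * h[kk]) +
    Y[kk + 1, , drop = FALSE] * h01 +
    m[kk + 1, , drop = FALSE] * (h11 * h[kk])
}

#' Apply the training-time augmentation chain to a clip
#'
#' Magnitude scaling then time warping, each with an independently drawn
#' random curve shared across all features (configurable per-feature). Labels
#' are carried by the caller and never touched here.
#'
#' @param clip `t x 46` clip matrix.
#' @param cfg An [augment_config()].
#' @return Augmented clip.
#' @export
augment_clip <- function(clip, cfg = augment_config()) {
  t_len <- nrow(clip)
  if (cfg$apply_magnitude) {
    curve <- if (cfg$per_feature)
      sapply(seq_len(ncol(clip)), function(i) random_curve(t_len, cfg))
    else random_curve(t_len, cfg)
    ac <- if (ncol(clip) == 46) 37:46 else integer(0)
    clip <- magnitude_scale(clip, curve, angle_cols = ac)
  }
  if (cfg$apply_warp) {
    clip <- time_warp(clip, random_curve(t_len, cfg), cfg$warp_floor)
    if (ncol(clip) == 46)       # clamp fp noise on the angle rows
      clip[, 37:46] <- pmin(pi, pmax(0, clip[, 37:46]))
  }
  clip
}
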