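#' Control parameters of the clip-attention classifier
#'
#' Architecture and training hyperparameters of the General Movements
#' classifier. The defaults reproduce the reference configuration: three
#' causal 1D convolutions (64 filters, kernel 3, ReLU, batch norm after the
#' activation, max pooling window/stride 4), a 64-unit fully connected layer
#' with dropout 0.5 before and after, sigmoid attention pooling over clips, a
#' final dropout on the pooled vector, a kernel-1 metadata convolution with 4
#' filters, and a 1-unit sigmoid output; trained with SGD (learning rate
#' 0.005, batch size 8, Nesterov momentum 0.9), l2 of 0.005 on weight kernels
#' only, label smoothing 0.1, minority oversampling x5, clips of 128 frames
#' with stride 8 and one sampled clip per video per epoch.
#'
#' @param n_conv,filters,kernel,pool_window Convolutional stack shape.
#' @param fc_units Units of the clip embedding layer.
#' @param dropout Dropout rate (applied before and after the fc layer and to
#'   the pooled vector before the output layer).
#' @param meta_filters Filters of the kernel-1 metadata convolution.
#' @param lr,batch_size,momentum SGD settings (Nesterov momentum).
#' @param l2 l2 penalty on weight kernels (not biases or batch-norm).
#' @param label_smoothing Symmetric label smoothing; targets become
#'   `y * (1 - ls) + ls/2`.
#' @param max_epochs,patience Epoch cap and early-stopping patience on
#'   validation loss; the parameters at minimum validation loss are retained.
#' @param oversample_factor Minority-class oversampling factor per epoch.
#' @param clip_t,clip_stride,s_train Clip length, inference stride, and clips
#'   sampled per video per training epoch.
#' @param eval_stride Clip stride used for the per-epoch validation pass
#'   (defaults to `clip_stride`; validation always uses the all-clip
#'   inference path so early stopping tracks the deployable model).
#' @param bn_momentum Running-statistics momentum of batch normalisation
#'   (statistics are frozen at inference).
#' @param use_meta Include the metadata branch (age + birth cohort); without
#'   it the model runs in movement-only mode.
#' @param augment An [augment_config()]; set
#'   `augment_config(apply_magnitude = FALSE, apply_warp = FALSE)` to disable
#'   training-time augmentation.
#' @param platt_on_logit Fit Platt scaling on the logit of the raw score (the
#'   pre-sigmoid margin) rather than the score itself.
#' @return A list of class `gma_control`.
#' @export
gma_control <- function(n_conv = 3L, filters = 64L, kernel = 3L,
                        pool_window = 4L, fc_units = 64L, dropout = 0.5,
                        meta_filters = 4L, lr = 0.005, batch_size = 8L,
                        momentum = 0.9, l2 = 0.005, label_smoothing = 0.1,
                        max_epochs = 10000L, patience = 100L,
                        oversample_factor = 5L, clip_t = 128L,
                        clip_stride = 8L, s_train = 1L,
                        eval_stride = clip_stride, bn_momentum = 0.99,
                        use_meta = TRUE, augment = augment_config(),
                        platt_on_logit = TRUE) {
  stopifnot(clip_t %% pool_window^n_conv == 0, dropout >= 0, dropout < 1,
            oversample_factor >= 1, s_train >= 1)
  structure(as.list(environment()), class = "gma_control")
}

#' Sigmoid attention pooling
#'
#' The attention module of the classifier, usable standalone: each clip
#' embedding `m_c` (row of `M`) is mapped to `u_c = tanh(W m_c + b)`, its
#' importance is `alpha_c = 1 / (1 + exp(-u_c' u))`, and the pooled
#' representation is the attention-weighted mean `v = (1/n) sum alpha_c m_c`.
#'
#' @param M `s x d` matrix of clip embeddings (one row per clip).
#' @param W `d x d` weight matrix; `b` length-`d` bias; `u` length-`d`
#'   context vector.
#' @return List with `v` (length-`d`) and `alpha` (length-`s`, in `[0, 1]`).
#' @export
attention_pool <- function(M, W, b, u) {
  M <- as.matrix(M)
  stopifnot(nrow(M) >= 1, ncol(M) == ncol(W), length(b) == nrow(W),
            length(u) == nrow(W))
  U <- tanh(M %*% t(W) + matrix(b, nrow(M), length(b), byrow = TRUE))
  alpha <- as.vector(1 / (1 + exp(-U %*% u)))
  v <- colSums(M * alpha) / nrow(M)
  list(v = v, alpha = alpha)
}

#' Metadata branch
#'
#' Applies the kernel-1, 4-filter 1D convolution to the length-2 metadata
#' vector (standardized age, binary cohort) treated as a 2-step, 1-channel
#' sequence, returning the flattened `2 x filters` output.
#'
#' @param meta Length-2 numeric vector `c(age_std, cohort01)`.
#' @param W Length-`filters` kernel weights; `b` length-`filters` bias.
#' @return Numeric vector of length `2 * filters`.
#' @export
metadata_branch <- function(meta, W, b) {
  stopifnot(length(meta) == 2, length(W) == length(b))
  c(meta[1] * W + b, meta[2] * W + b)
}

#' Minority oversampling index vector
#'
#' Per-epoch sample list: every majority-class video once, every
#' minority-class video `factor` times, so a 408/76 class split at the
#' default factor 5 yields 408 vs 380 per-epoch samples — approximately
#' equal representation of the two groups.
#'
#' @param y Binary label vector.
#' @param factor Oversampling factor (default 5).
#' @return Integer vector of video indices (unshuffled).
#' @export
oversample_indices <- function(y, factor = 5L) {
  if (length(unique(y)) < 2) return(seq_along(y))
  n1 <- sum(y == 1)
  if (n1 * 2 == length(y)) return(seq_along(y))   # already balanced
  minority <- if (n1 < length(y) - n1) 1 else 0
  c(which(y != minority), rep(which(y == minority), factor))
}

#' Early-stopping rule
#'
#' Given a sequence of per-epoch validation losses, returns the epoch whose
#' parameters are retained (minimum loss) and the epoch at which training
#' stops (no improvement for `patience` epochs, or the end of the trace).
#'
#' @param losses Numeric vector of validation losses by epoch.
#' @param patience Patience in epochs.
#' @return List with `best_epoch` and `stop_epoch`.
#' @export
early_stop <- function(losses, patience) {
  best <- 1
  for (e in seq_along(losses)) {
    if (losses[e] < losses[best]) best <- e
    if (e - best >= patience) return(list(best_epoch = best, stop_epoch = e))
  }
  list(best_epoch = best, stop_epoch = length(losses))
}

#' Platt scaling calibration
#'
#' Fits a logistic regression of the binary labels on the classifier's raw
#' validation scores (by default on their logit, the pre-sigmoid margin);
#' the fitted slope/intercept transform raw scores into calibrated
#' probabilities at inference. The transform is monotone increasing whenever
#' the slope is positive.
#'
#' @param scores Raw validation scores in (0, 1).
#' @param labels Binary labels (both classes must be present).
#' @param on_logit Fit on `qlogis(score)` (default) or the raw score.
#' @return List of class `platt_calibrator` with `a` (slope), `c`
#'   (intercept), `on_logit`.
#' @export
fit_platt <- function(scores, labels, on_logit = TRUE) {
  if (length(unique(labels)) < 2)
    stop("Platt scaling requires both classes in the validation set")
  if (stats::sd(scores) < 1e-12)
    warning("constant validation scores: Platt fit is degenerate")
  x <- if (on_logit) stats::qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12))
  else scores
  fit <- suppressWarnings(stats::glm.fit(cbind(1, x), labels,
                                         family = stats::binomial()))
  structure(list(a = fit$coefficients[2], c = fit$coefficients[1],
                 on_logit = on_logit),
            class = "platt_calibrator")
}

#' @param calib A `platt_calibrator`.
#' @rdname fit_platt
#' @export
apply_platt <- function(calib, scores) {
  x <- if (calib$on_logit) stats::qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12))
  else scores
  as.vector(1 / (1 + exp(-(calib$a * x + calib$c))))
}

# standardize metadata into the model's 2-column numeric form
.meta_matrix <- function(meta, scaling) {
  if (is.null(meta)) return(NULL)
  age <- (meta$age_weeks - scaling$age_mean) / scaling$age_sd
  cohort <- as.numeric(meta$cohort == "preterm")
  cbind(age, cohort)
}

# stack clips with the given 0-based starts into the network's feature-major
# p x (s*t) layout (clips in contiguous column blocks)
.stack_clips <- function(vals, starts, t) {
  cols <- as.vector(outer(seq_len(t), starts, `+`))
  vals[, cols, drop = FALSE]
}

# all-clip inference forward for one video; returns score and attention
.video_forward <- function(params, vals, meta_row, ctrl, stride = NULL,
                           keep_cache = FALSE) {
  if (is.null(stride)) stride <- ctrl$clip_stride
  n <- ncol(vals)
  starts <- seq(0L, n - ctrl$clip_t, by = stride)
  X <- .stack_clips(vals, starts, ctrl$clip_t)
  fw <- nn_forward(params, X, B = length(starts),
                   groups = rep(1L, length(starts)),
                   meta = if (is.null(meta_row)) NULL else rbind(meta_row),
                   cfg = ctrl, training = FALSE)
  list(score = fw$score, alpha = fw$cache$alpha, starts = starts,
       cache = if (keep_cache) fw$cache else NULL)
}

#' Fit the General Movements clip-attention classifier
#'
#' Trains the causal-convolution attention network on preprocessed feature
#' matrices. Each epoch samples one clip per video (minority-class videos
#' oversampled), augments it (magnitude scaling + time warping), and takes
#' SGD steps on the smoothed binary cross-entropy; validation loss is
#' computed each epoch with the all-clip inference path, early stopping
#' retains the parameters with minimum validation loss, and Platt scaling is
#' then fitted on the validation scores.
#'
#' @param features List of [feature_matrix()] objects (or bare `46 x n`
#'   matrices), the training videos.
#' @param y Binary labels (0 normal, 1 abnormal/absent), one per video.
#' @param meta Optional data.frame with columns `age_weeks` and `cohort`
#'   (`"preterm"`/`"term"`); omit for movement-only mode.
#' @param validation List with elements `features`, `y` and (if `meta` was
#'   given) `meta`: the held-out validation videos driving early stopping and
#'   calibration.
#' @param control A [gma_control()].
#' @param seed Integer seed for weight initialisation, clip sampling,
#'   augmentation and dropout.
#' @return An object of class `gma_fit` with elements `params`, `control`,
#'   `platt`, `history` (per-epoch train/validation loss), `best_epoch`,
#'   `meta_scaling`, `val_scores`.
#' @export
gma_fit <- function(features, y, meta = NULL, validation, control = gma_control(),
                    seed = NULL) {
  stopifnot(inherits(control, "gma_control"))
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("training set must contain both classes")
  ctrl <- control
  ctrl$use_meta <- ctrl$use_meta && !is.null(meta)
  vals_list <- lapply(features, function(f)
    if (inherits(f, "feature_matrix")) f$values else as.matrix(f))
  val_vals <- lapply(validation$features, function(f)
    if (inherits(f, "feature_matrix")) f$values else as.matrix(f))
  y_val <- as.integer(validation$y)

  scaling <- list(age_mean = 0, age_sd = 1)
  meta_mat <- val_meta_mat <- NULL
  if (ctrl$use_meta) {
    scaling <- list(age_mean = mean(meta$age_weeks),
                    age_sd = max(stats::sd(meta$age_weeks), 1e-8))
    meta_mat <- .meta_matrix(meta, scaling)
    val_meta_mat <- .meta_matrix(validation$meta, scaling)
  }

  with_seed(seed, {
    params <- nn_init(nrow(vals_list[[1]]), ctrl)
    state <- list()
    ysm <- y * (1 - ctrl$label_smoothing) + ctrl$label_smoothing / 2
    base_idx <- oversample_indices(y, ctrl$oversample_factor)
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    best <- list(epoch = 0L, loss = Inf, params = params)
    t_len <- ctrl$clip_t

    for (epoch in seq_len(ctrl$max_epochs)) {
      idx <- sample(base_idx)
      ep_loss <- 0; n_batches <- 0
      for (b0 in seq(1, length(idx), by = ctrl$batch_size)) {
        bi <- idx[b0:min(b0 + ctrl$batch_size - 1, length(idx))]
        nv <- length(bi)
        clips <- vector("list", nv * ctrl$s_train)
        ci <- 0
        for (v in bi) {
          cl <- sample_training_clips(vals_list[[v]], t = t_len,
                                      stride = ctrl$clip_stride,
                                      s = ctrl$s_train)
          for (one in cl) {
            ci <- ci + 1
            clips[[ci]] <- augment_clip(one, ctrl$augment)
          }
        }
        X <- t(do.call(rbind, clips))
        groups <- rep(seq_len(nv), each = ctrl$s_train)
        fw <- nn_forward(params, X, B = nv * ctrl$s_train, groups = groups,
                         meta = if (ctrl$use_meta)
                           meta_mat[bi, , drop = FALSE] else NULL,
                         cfg = ctrl, training = TRUE)
        params <- fw$params
        p_hat <- pmin(pmax(fw$score, 1e-12), 1 - 1e-12)
        tgt <- ysm[bi]
        ep_loss <- ep_loss - mean(tgt * log(p_hat) + (1 - tgt) * log(1 - p_hat))
        n_batches <- n_batches + 1
        dlogit <- (fw$score - tgt) / nv
        bw <- nn_backward(params, fw$cache, dlogit, ctrl)
        up <- nn_update(params, bw$grads, state, ctrl)
        params <- up$params; state <- up$state
      }
      # validation with the deployable all-clip inference path
      val_scores <- vapply(seq_along(val_vals), function(i)
        .video_forward(params, val_vals[[i]],
                       if (ctrl$use_meta) val_meta_mat[i, ] else NULL,
                       ctrl, stride = ctrl$eval_stride)$score, 0)
      vs <- pmin(pmax(val_scores, 1e-12), 1 - 1e-12)
      val_loss <- -mean(y_val * log(vs) + (1 - y_val) * log(1 - vs))
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = ep_loss / n_batches,
                                           val_loss = val_loss))
      if (val_loss < best$loss)
        best <- list(epoch = epoch, loss = val_loss, params = params)
      .log(sprintf("epoch %d train %.4f val %.4f (best %.4f @ %d)",
                   epoch, ep_loss / n_batches, val_loss, best$loss,
                   best$epoch), level = 2L)
      if (epoch - best$epoch >= ctrl$patience) break
    }

    params <- best$params
    raw_val <- vapply(seq_along(val_vals), function(i)
      .video_forward(params, val_vals[[i]],
                     if (ctrl$use_meta) val_meta_mat[i, ] else NULL,
                     ctrl, stride = ctrl$eval_stride)$score, 0)
    platt <- fit_platt(raw_val, y_val, on_logit = ctrl$platt_on_logit)

    structure(
      list(params = params, control = ctrl, platt = platt,
           history = history, best_epoch = best$epoch,
           meta_scaling = scaling, use_meta = ctrl$use_meta,
           val_scores = data.frame(raw = raw_val, y = y_val),
           n_train = length(vals_list)),
      class = "gma_fit")
  })
}

#' Predict GMs class for one preprocessed video
#'
#' Splits the video into all overlapping inference clips (547 for a standard
#' 4500-frame video), pools them through the trained attention module in one
#' pass, applies the Platt calibrator and thresholds at 0.5 (abnormal when
#' the calibrated probability is at least 0.5).
#'
#' @param object A fitted [gma_fit()] model.
#' @param fm A [feature_matrix()] (videos failing quality control are
#'   refused).
#' @param meta One-row data.frame with `age_weeks` and `cohort` (required if
#'   the model uses metadata).
#' @return List of class `gma_prediction`: `video_id`, `raw_score`,
#'   `calibrated_prob`, `label`, `alpha` (per-clip attention weights),
#'   `clip_starts`.
#' @export
predict_video <- function(object, fm, meta = NULL) {
  stopifnot(inherits(object, "gma_fit"))
  qc <- attr(fm, "qc")
  if (!is.null(qc) && !isTRUE(qc$pass))
    stop("video ", if (inherits(fm, "feature_matrix")) fm$video_id else "",
         " failed quality control; refusing to predict")
  vals <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  meta_row <- NULL
  if (object$use_meta) {
    if (is.null(meta)) stop("model was fitted with metadata; `meta` is required")
    meta_row <- .meta_matrix(meta, object$meta_scaling)[1, ]
  }
  vf <- .video_forward(object$params, vals, meta_row, object$control)
  cal <- apply_platt(object$platt, vf$score)
  structure(
    list(video_id = if (inherits(fm, "feature_matrix")) fm$video_id else NA,
         raw_score = vf$score, calibrated_prob = cal,
         label = as.integer(cal >= 0.5), alpha = vf$alpha,
         clip_starts = vf$starts),
    class = "gma_prediction")
}

#' @export
print.gma_prediction <- function(x, ...) {
  cat(sprintf("<gma_prediction> %s: raw %.3f calibrated %.3f -> %s (%d clips)\n",
              x$video_id, x$raw_score, x$calibrated_prob,
              if (x$label == 1) "abnormal/absent" else "normal",
              length(x$alpha)))
  invisible(x)
}

#' Vanilla gradient saliency of a video
#'
#' Absolute gradient of the raw (pre-calibration) video score with respect to
#' every input element, summed over frames within each clip per feature.
#'
#' @inheritParams predict_video
#' @return List of class `gma_saliency`: `map` (`46 x n_clips` matrix),
#'   `clip_totals` (per-clip sum over features), `point_average` (mean over
#'   clips of each body point's x+y rows), `clip_starts`.
#' @export
saliency <- function(object, fm, meta = NULL) {
  stopifnot(inherits(object, "gma_fit"))
  vals <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  meta_row <- NULL
  if (object$use_meta) {
    if (is.null(meta)) stop("model was fitted with metadata; `meta` is required")
    meta_row <- .meta_matrix(meta, object$meta_scaling)[1, ]
  }
  ctrl <- object$control
  vf <- .video_forward(object$params, vals, meta_row, ctrl, keep_cache = TRUE)
  p <- vf$score
  bw <- nn_backward(object$params, vf$cache, dlogit = p * (1 - p), ctrl,
                    want_dX = TRUE)
  g <- abs(bw$dX)                      # 46 x (s*t), clips in column blocks
  s <- length(vf$starts); t_len <- ctrl$clip_t
  map <- vapply(seq_len(s), function(c_)
    rowSums(g[, ((c_ - 1) * t_len + 1):(c_ * t_len), drop = FALSE]),
    numeric(nrow(g)))                  # 46 x s
  rownames(map) <- feature_row_names()
  totals <- colSums(map)
  bp <- body_points()
  pt_avg <- vapply(seq_along(bp), function(j)
    mean(map[2 * j - 1, ] + map[2 * j, ]), 0)
  names(pt_avg) <- bp
  structure(list(map = map, clip_totals = totals, point_average = pt_avg,
                 clip_starts = vf$starts),
            class = "gma_saliency")
}

#' Per-clip embeddings through the convolutional backbone
#'
#' Runs clips through the trained causal-convolution stack and fully
#' connected layer (inference mode: frozen batch-norm statistics, no
#' dropout), returning the clip embeddings `m_c` that feed the attention
#' module, with the intermediate per-stage activations available for
#' inspection.
#'
#' @param object A [gma_fit()] model, or a raw parameter list from the
#'   internal initialiser.
#' @param clips List of `t x 46` clip matrices (see [make_clips()]).
#' @param control A [gma_control()] (taken from the model when available).
#' @return List with `M` (`s x fc_units` embedding matrix), `flat`
#'   (`s x flat` pre-fc concatenated features) and `stage_dims` (temporal
#'   length after each conv+pool stage).
#' @export
conv_backbone <- function(object, clips, control = NULL) {
  if (inherits(object, "gma_fit")) {
    params <- object$params; ctrl <- object$control
  } else {
    params <- object; ctrl <- control
  }
  stopifnot(!is.null(ctrl))
  if (is.matrix(clips)) clips <- list(clips)
  bad <- which(vapply(clips, nrow, 0L) != ctrl$clip_t)
  if (length(bad))
    stop("clip length must be ", ctrl$clip_t, " frames (clip ", bad[1], ")")
  B <- length(clips)
  X <- t(do.call(rbind, clips))
  # a zero metadata row keeps the output layer's shape; it cannot affect the
  # embeddings, which are read from the cache upstream of it
  meta <- if (is.null(params$meta)) NULL else matrix(0, B, 2)
  fw <- nn_forward(params, X, B = B, groups = seq_len(B), meta = meta,
                   cfg = ctrl, training = FALSE)
  t_dims <- ctrl$clip_t / ctrl$pool_window^seq_len(ctrl$n_conv)
  list(M = t(fw$cache$m_c), flat = t(fw$cache$Mflat), stage_dims = t_dims)
}
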