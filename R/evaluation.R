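#' Grouped, stratified train/validation/test splits
#'
#' Repeated random splitting into train/validation/test subsets by video
#' count fractions (default 70/15/15), keeping all videos of one infant in
#' the same subset in every repeat, and stratifying by the binary GMs label
#' so class proportions are similar across subsets.
#'
#' @param labels data.frame with columns `video_id`, a group column and a
#'   binary label column.
#' @param n_repeats Number of independent repeats (default 25).
#' @param fractions Length-3 numeric (train, validation, test) summing to 1.
#' @param group_col,label_col Column names (defaults `infant_id`,
#'   `gms_binary`).
#' @param seed Integer seed; repeat `r` uses `seed + r` so the full plan is
#'   reproducible.
#' @return List of `n_repeats` lists, each with character vectors `train`,
#'   `val`, `test` of video ids.
#' @export
make_splits <- function(labels, n_repeats = 25L,
                        fractions = c(0.70, 0.15, 0.15),
                        group_col = "infant_id", label_col = "gms_binary",
                        seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, all(fractions > 0))
  groups <- split(labels$video_id, labels[[group_col]])
  glab <- vapply(split(labels[[label_col]], labels[[group_col]]), max, 0)
  n <- nrow(labels)
  test_target <- fractions[3] * n
  big <- vapply(groups, length, 0L) > ceiling(test_target)
  if (any(big))
    stop("group(s) larger than the test set: ",
         paste(names(groups)[big], collapse = ", "))
  one_repeat <- function(r) {
    set.seed(seed + r)
    out <- list(train = character(0), val = character(0), test = character(0))
    for (cls in unique(glab)) {
      gs <- sample(names(groups)[glab == cls])
      sizes <- vapply(groups[gs], length, 0L)
      n_cls <- sum(sizes)
      t_test <- fractions[3] * n_cls
      t_val <- fractions[2] * n_cls
      cum <- cumsum(sizes)
      k_test <- which(cum >= t_test)[1]
      rest <- if (k_test < length(gs)) (k_test + 1):length(gs) else integer(0)
      cum2 <- cumsum(sizes[rest])
      k_val <- if (length(rest)) which(cum2 >= t_val)[1] else 0L
      if (is.na(k_val)) k_val <- length(rest)
      test_g <- gs[seq_len(k_test)]
      val_g <- if (k_val > 0) gs[rest[seq_len(k_val)]] else character(0)
      train_g <- setdiff(gs, c(test_g, val_g))
      out$test <- c(out$test, unlist(groups[test_g], use.names = FALSE))
      out$val <- c(out$val, unlist(groups[val_g], use.names = FALSE))
      out$train <- c(out$train, unlist(groups[train_g], use.names = FALSE))
    }
    out
  }
  lapply(seq_len(n_repeats), one_repeat)
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the ROC curve over the unique score
#' thresholds; identical to the rank-based (Mann-Whitney) estimator.
#'
#' @param scores Numeric prediction scores (larger = more abnormal).
#' @param labels Binary labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("AUC is undefined for single-class labels")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)   # one point per unique threshold
  tpr <- c(0, tp[last] / sum(y))
  fpr <- c(0, fp[last] / sum(1 - y))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Classification performance metrics
#'
#' AUC (trapezoidal ROC), balanced accuracy, sensitivity, specificity, PPV
#' and NPV at the given threshold, with the abnormal class (label 1) as the
#' positive class. With single-class labels the AUC is `NA` with a warning;
#' the confusion-matrix metrics are still computed where defined.
#'
#' @param scores Calibrated probabilities (or any monotone score).
#' @param labels Binary labels (1 = abnormal/absent).
#' @param threshold Decision threshold (default 0.5; positive when
#'   `score >= threshold`).
#' @return One-row data.frame: auc, balanced_accuracy, sensitivity,
#'   specificity, ppv, npv.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  auc <- tryCatch(auc_roc(scores, labels), error = function(e) {
    warning(conditionMessage(e)); NA_real_
  })
  data.frame(
    auc = auc,
    balanced_accuracy = (sens + spec) / 2,
    sensitivity = sens, specificity = spec,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Aggregate per-repeat test predictions into one label per video
#'
#' Each video typically appears in several held-out test sets across the
#' cross-validation repeats; the consensus label is the most frequent
#' predicted label, with ties broken toward abnormal (screening-conservative),
#' alongside the median prediction value.
#'
#' @param predictions data.frame with columns `video_id`, `label` and a score
#'   column (default `calibrated_prob`).
#' @param all_ids Optional vector of every video id; ids never appearing in a
#'   test set are reported in the `excluded` attribute.
#' @param score_col Name of the score column to take medians over.
#' @return data.frame: `video_id`, `n_appearances`, `label`
#'   (majority, ties toward 1), `median_score`; attribute `excluded`.
#' @export
aggregate_labels <- function(predictions, all_ids = NULL,
                             score_col = "calibrated_prob") {
  sp <- split(predictions, predictions$video_id)
  rows <- lapply(sp, function(d) {
    n1 <- sum(d$label == 1); n0 <- sum(d$label == 0)
    data.frame(video_id = d$video_id[1], n_appearances = nrow(d),
               label = as.integer(n1 >= n0),
               median_score = stats::median(d[[score_col]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  excluded <- if (is.null(all_ids)) character(0)
  else setdiff(all_ids, out$video_id)
  if (length(excluded))
    .log("videos never in a test set (excluded): ",
         paste(excluded, collapse = ", "))
  attr(out, "excluded") <- excluded
  out
}

#' Displacement statistics of high- vs low-saliency clips
#'
#' Compares the movement content of clips the model attends to most and
#' least: clips at or above the 90th percentile of total saliency (pooled
#' over the supplied videos) form the high set, those at or below the 10th
#' percentile the low set (ties included on both boundaries). For each clip
#' the body-point displacement from the per-video average position (mean of
#' each point's coordinates over all frames) is summarised as the mean over
#' frames and points of the displacement magnitude, and as the mean over
#' points of the per-point SD of displacement over frames.
#'
#' @param sal_list List of per-video numeric vectors of clip saliency totals
#'   (see [saliency()]), aligned with clips from [make_clips()] at the same
#'   `t`/`stride`.
#' @param fm_list List of the corresponding [feature_matrix()] objects.
#' @param t,stride Clip geometry (defaults 128 / 8).
#' @param hi,lo Percentile boundaries (defaults 0.9 and 0.1).
#' @return List with `high` and `low` (data.frames: video, clip, start,
#'   mean_disp, sd_disp), `median_diff_mean` and `median_diff_sd`
#'   (high minus low).
#' @export
saliency_clip_analysis <- function(sal_list, fm_list, t = 128L, stride = 8L,
                                   hi = 0.9, lo = 0.1) {
  stopifnot(length(sal_list) == length(fm_list))
  all_tot <- unlist(sal_list, use.names = FALSE)
  if (length(all_tot) < 10)
    stop("saliency analysis needs at least 10 clips, got ", length(all_tot))
  q_hi <- stats::quantile(all_tot, hi, names = FALSE)
  q_lo <- stats::quantile(all_tot, lo, names = FALSE)
  rows <- list()
  for (v in seq_along(fm_list)) {
    fm <- fm_list[[v]]
    vals <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
    xs <- vals[seq(1, 35, by = 2), , drop = FALSE]
    ys <- vals[seq(2, 36, by = 2), , drop = FALSE]
    disp <- sqrt((xs - rowMeans(xs))^2 + (ys - rowMeans(ys))^2)  # 18 x n
    starts <- seq(0L, ncol(vals) - t, by = stride)
    tot <- sal_list[[v]]
    stopifnot(length(tot) == length(starts))
    for (c_ in seq_along(starts)) {
      d <- disp[, (starts[c_] + 1):(starts[c_] + t), drop = FALSE]
      rows[[length(rows) + 1]] <- data.frame(
        video = v, clip = c_, start = starts[c_], total = tot[c_],
        mean_disp = mean(d), sd_disp = mean(apply(d, 1, stats::sd)))
    }
  }
  df <- do.call(rbind, rows)
  high <- df[df$total >= q_hi, , drop = FALSE]
  low <- df[df$total <= q_lo, , drop = FALSE]
  list(high = high, low = low,
       median_diff_mean = stats::median(high$mean_disp) -
         stats::median(low$mean_disp),
       median_diff_sd = stats::median(high$sd_disp) -
         stats::median(low$sd_disp))
}

#' Repeated grouped cross-validation of the classifier
#'
#' Runs the full evaluation protocol: for each repeat, a grouped stratified
#' 70/15/15 split, model fitting with early stopping and Platt calibration,
#' prediction of the held-out test videos, and performance metrics.
#'
#' @param features Named list of [feature_matrix()] objects (names =
#'   video ids), or unnamed in `labels$video_id` order.
#' @param labels data.frame with `video_id`, `infant_id`, `gms_binary` and
#'   (if metadata is used) `age_weeks`, `cohort`.
#' @param control A [gma_control()].
#' @param n_repeats Number of repeats (default 25).
#' @param fractions Train/validation/test fractions.
#' @param seed Base seed; repeat r derives its split and fit seeds from it.
#' @return List with `metrics` (one row per repeat), `summary` (mean and SD
#'   per metric), `predictions` (per-repeat test predictions, suitable for
#'   [aggregate_labels()]) and `splits`.
#' @export
run_cv <- function(features, labels, control = gma_control(),
                   n_repeats = 25L, fractions = c(0.70, 0.15, 0.15),
                   seed = 1L) {
  if (is.null(names(features))) names(features) <- labels$video_id
  splits <- make_splits(labels, n_repeats, fractions, seed = seed)
  use_meta <- control$use_meta && all(c("age_weeks", "cohort") %in% names(labels))
  meta_of <- function(ids) if (use_meta)
    labels[match(ids, labels$video_id), c("age_weeks", "cohort")] else NULL
  y_of <- function(ids) labels$gms_binary[match(ids, labels$video_id)]
  metrics <- list(); preds <- list()
  for (r in seq_len(n_repeats)) {
    sp <- splits[[r]]
    fit <- gma_fit(features[sp$train], y_of(sp$train), meta = meta_of(sp$train),
                   validation = list(features = features[sp$val],
                                     y = y_of(sp$val),
                                     meta = meta_of(sp$val)),
                   control = control, seed = seed + 1000L + r)
    pr <- predict(fit, features[sp$test], meta = meta_of(sp$test))
    pr$video_id <- sp$test
    pr$repeat_id <- r
    y_test <- y_of(sp$test)
    metrics[[r]] <- cbind(repeat_id = r,
                          compute_metrics(pr$calibrated_prob, y_test))
    preds[[r]] <- pr
    .log(sprintf("repeat %d: AUC %.3f", r, metrics[[r]]$auc))
  }
  m <- do.call(rbind, metrics)
  summ <- data.frame(
    metric = setdiff(names(m), "repeat_id"),
    mean = vapply(setdiff(names(m), "repeat_id"),
                  function(k) mean(m[[k]], na.rm = TRUE), 0),
    sd = vapply(setdiff(names(m), "repeat_id"),
                function(k) stats::sd(m[[k]], na.rm = TRUE), 0))
  rownames(summ) <- NULL
  list(metrics = m, summary = summ, predictions = do.call(rbind, preds),
       splits = splits)
}
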