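#' @export
print.gma_fit <- function(x, ...) {
  cat("General Movements clip-attention classifier\n")
  cat(sprintf("  trained on %d videos (%s)\n", x$n_train,
              if (x$use_meta) "movement + metadata" else "movement only"))
  cat(sprintf("  epochs run: %d; parameters retained from epoch %d (val loss %.4f)\n",
              nrow(x$history), x$best_epoch,
              x$history$val_loss[x$best_epoch]))
  cat(sprintf("  Platt calibrator: slope %.3f, intercept %.3f\n",
              x$platt$a, x$platt$c))
  invisible(x)
}

#' @export
summary.gma_fit <- function(object, ...) {
  h <- object$history
  co <- coef(object)
  npar <- sum(vapply(co, length, 0L))
  structure(list(n_train = object$n_train, use_meta = object$use_meta,
                 epochs = nrow(h), best_epoch = object$best_epoch,
                 best_val_loss = h$val_loss[object$best_epoch],
                 final_train_loss = h$train_loss[nrow(h)],
                 n_parameters = npar, platt = object$platt,
                 val_scores = object$val_scores),
            class = "summary.gma_fit")
}

#' @export
print.summary.gma_fit <- function(x, ...) {
  cat("General Movements clip-attention classifier\n")
  cat(sprintf("  videos: %d | inputs: %s | parameters: %d\n", x$n_train,
              if (x$use_meta) "movement + metadata" else "movement only",
              x$n_parameters))
  cat(sprintf("  epochs: %d (best %d, val loss %.4f; final train loss %.4f)\n",
              x$epochs, x$best_epoch, x$best_val_loss, x$final_train_loss))
  cat(sprintf("  calibration: p = plogis(%.3f * margin + %.3f)\n",
              x$platt$a, x$platt$c))
  if (nrow(x$val_scores) > 0)
    cat(sprintf("  validation raw scores: %.3f-%.3f over %d videos\n",
                min(x$val_scores$raw), max(x$val_scores$raw),
                nrow(x$val_scores)))
  invisible(x)
}

#' Model parameters of a fitted classifier
#'
#' @param object A [gma_fit()] model.
#' @param ... Unused.
#' @return Named list of numeric arrays: per-conv-stage kernels/biases and
#'   batch-norm parameters, fully connected layer, attention parameters
#'   (`W`, `b`, context vector `u`), metadata kernel and output layer.
#' @export
coef.gma_fit <- function(object, ...) {
  p <- object$params
  out <- list()
  for (l in seq_along(p$conv)) {
    for (nm in c("W", "b", "gamma", "beta"))
      out[[paste0("conv", l, "_", nm)]] <- p$conv[[l]][[nm]]
  }
  out$fc_W <- p$fc$W; out$fc_b <- p$fc$b
  out$att_W <- p$att$W; out$att_b <- p$att$b; out$att_u <- p$att$u
  if (!is.null(p$meta)) { out$meta_W <- p$meta$W; out$meta_b <- p$meta$b }
  out$out_W <- p$out$W; out$out_b <- p$out$b
  out
}

#' Training history plot
#'
#' Training and validation loss by epoch, with the retained (minimum
#' validation loss) epoch marked.
#'
#' @param x A [gma_fit()] model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.gma_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Predict method for the GMs classifier
#'
#' @param object A [gma_fit()] model.
#' @param features List of [feature_matrix()] objects (or one).
#' @param meta Optional data.frame of metadata rows aligned with `features`.
#' @param ... Unused.
#' @return data.frame with columns `video_id`, `raw_score`,
#'   `calibrated_prob`, `label`.
#' @export
predict.gma_fit <- function(object, features, meta = NULL, ...) {
  if (inherits(features, "feature_matrix") || is.matrix(features))
    features <- list(features)
  rows <- lapply(seq_along(features), function(i) {
    pr <- predict_video(object, features[[i]],
                        if (is.null(meta)) NULL else meta[i, , drop = FALSE])
    data.frame(video_id = pr$video_id, raw_score = pr$raw_score,
               calibrated_prob = pr$calibrated_prob, label = pr$label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Residuals of a fitted classifier
#'
#' Response residuals (`label - calibrated probability`) on the validation
#' videos used for early stopping and calibration.
#'
#' @param object A [gma_fit()] model.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
residuals.gma_fit <- function(object, ...) {
  cal <- apply_platt(object$platt, object$val_scores$raw)
  object$val_scores$y - cal
}
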