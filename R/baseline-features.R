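# Canonical time-series feature set for the logistic-regression baseline:
# the 22 "catch" dynamical features widely used for time-series
# classification, plus the mean and standard deviation of the raw series
# (the 24-feature convention). The 22 dynamical features are computed on the
# z-scored series, following their published definitions; mean and SD are of
# the raw series. Constant series return zeros for the dynamical block.

.zscore <- function(y) {
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0) return(NULL)
  (y - mean(y)) / s
}

.acf_vec <- function(y, lag_max) {
  as.vector(stats::acf(y, lag.max = lag_max, plot = FALSE,
                       demean = TRUE)$acf)[-1]
}

# first 1/e crossing of the ACF, linearly interpolated
.f1ecac <- function(y) {
  n <- length(y)
  a <- .acf_vec(y, min(n - 2, 400))
  th <- exp(-1)
  below <- which(a < th)
  if (!length(below)) return(length(a) + 1)
  k <- below[1]
  prev <- if (k == 1) 1 else a[k - 1]
  (k - 1) + (prev - th) / (prev - a[k]) # interpolate between lags k-1 and k
}

.first_min_acf <- function(y) {
  a <- .acf_vec(y, min(length(y) - 2, 400))
  for (i in 2:(length(a) - 1)) if (a[i] < a[i - 1] && a[i] < a[i + 1]) return(i)
  length(a)
}

.first_zero_acf <- function(y) {
  a <- .acf_vec(y, min(length(y) - 2, 400))
  z <- which(a < 0)
  if (!length(z)) length(a) else z[1]
}

.hist_mode <- function(y, nbins) {
  br <- seq(min(y), max(y), length.out = nbins + 1)
  h <- findInterval(y, br, rightmost.closed = TRUE)
  counts <- tabulate(h, nbins)
  centers <- (br[-1] + br[-(nbins + 1)]) / 2
  mean(centers[counts == max(counts)])
}

.longstretch <- function(bin, value) {
  r <- rle(bin)
  len <- r$lengths[r$values == value]
  if (!length(len)) 0 else max(len)
}

.outlier_include_mdrmd <- function(y) {
  n <- length(y)
  mx <- max(y)
  if (mx <= 0) return(0)
  ths <- seq(0, mx, by = 0.01)
  keep_min <- max(2, ceiling(0.02 * n))
  md <- c()
  for (th in ths) {
    r <- which(y >= th)
    if (length(r) < keep_min) break
    md <- c(md, stats::median(r) / n - 0.5)
  }
  if (!length(md)) 0 else stats::median(md)
}

.spectrum_rect <- function(y) {
  # rectangular-window power spectrum via the periodogram
  n <- length(y)
  P <- Mod(stats::fft(y))^2 / n
  nf <- floor(n / 2)
  list(S = P[2:(nf + 1)], w = 2 * pi * (1:nf) / n)   # angular frequency
}

.ami_even <- function(y, lag, nbins) {
  n <- length(y)
  a <- y[1:(n - lag)]; b <- y[(1 + lag):n]
  br <- seq(min(y), max(y), length.out = nbins + 1)
  ia <- findInterval(a, br, rightmost.closed = TRUE)
  ib <- findInterval(b, br, rightmost.closed = TRUE)
  jt <- table(factor(ia, 1:nbins), factor(ib, 1:nbins)) / length(a)
  px <- rowSums(jt); py <- colSums(jt)
  s <- 0
  for (i in 1:nbins) for (j in 1:nbins) {
    if (jt[i, j] > 0) s <- s + jt[i, j] * log(jt[i, j] / (px[i] * py[j]))
  }
  s
}

.gaussian_ami_fmmi <- function(y, lag_max = 40) {
  lag_max <- min(lag_max, length(y) - 2)
  a <- .acf_vec(y, lag_max)
  ami <- -0.5 * log(pmax(1 - a^2, 1e-12))
  for (i in 2:(length(ami) - 1))
    if (ami[i] < ami[i - 1] && ami[i] < ami[i + 1]) return(i)
  length(ami)
}

.motif_three_hh <- function(y) {
  q <- stats::quantile(y, c(1 / 3, 2 / 3), names = FALSE, type = 8)
  s <- findInterval(y, q) + 1L            # 1, 2, 3
  pairs <- table(factor(s[-length(s)], 1:3), factor(s[-1], 1:3))
  p <- pairs / sum(pairs)
  -sum(p[p > 0] * log(p[p > 0]))
}

.local_simple_stderr <- function(y, train = 3) {
  n <- length(y)
  if (n <= train + 1) return(0)
  pred <- vapply((train + 1):n, function(i) mean(y[(i - train):(i - 1)]), 0)
  stats::sd(y[(train + 1):n] - pred)
}

.tauresrat <- function(y) {
  res <- diff(y)
  .first_zero_acf(res) / .first_zero_acf(y)
}

.embed2_expfit_meandiff <- function(y) {
  tau <- max(1, round(.f1ecac(y)))
  n <- length(y) - tau
  if (n < 10) return(0)
  a <- y[1:n]; b <- y[(1 + tau):(n + tau)]
  d <- sqrt(diff(a)^2 + diff(b)^2)
  if (!length(d) || mean(d) == 0) return(0)
  h <- graphics::hist(d, breaks = 10, plot = FALSE)
  mids <- h$mids
  emp <- h$density
  theo <- stats::dexp(mids, rate = 1 / mean(d))
  mean(abs(emp - theo))
}

# two-regime linear fit of log fluctuation vs log window size: proportion of
# window sizes assigned to the first (small-scale) regime at the best split
.fluct_prop_r1 <- function(y, how = c("dfa", "rsrange")) {
  how <- match.arg(how)
  n <- length(y)
  x <- cumsum(y - mean(y))
  taus <- unique(round(exp(seq(log(5), log(floor(n / 2)), length.out = 50))))
  taus <- taus[taus >= 5]
  if (length(taus) < 4) return(0)
  Fv <- vapply(taus, function(tau) {
    nw <- floor(n / tau)
    if (nw < 1) return(NA_real_)
    # all windows detrended at once: residual = (I - H) seg, shared hat matrix
    Xw <- matrix(x[seq_len(nw * tau)], tau, nw)
    A <- cbind(1, seq_len(tau))
    beta <- solve(crossprod(A), crossprod(A, Xw))     # 2 x nw
    Res <- Xw - A %*% beta
    if (how == "dfa") mean(sqrt(colMeans(Res^2)))
    else mean(apply(Res, 2, max) - apply(Res, 2, min))
  }, 0)
  ok <- is.finite(Fv) & Fv > 0
  taus <- taus[ok]; Fv <- Fv[ok]
  k <- length(taus)
  if (k < 4) return(0)
  lx <- log(taus); ly <- log(Fv)
  sse <- function(i, j) {
    if (j - i < 1) return(0)
    f <- stats::lm.fit(cbind(1, lx[i:j]), ly[i:j])
    sum(f$residuals^2)
  }
  best <- which.min(vapply(2:(k - 1), function(s) sse(1, s) + sse(s + 1, k), 0))
  (best + 1) / k
}

.transition_sumdiagcov <- function(y) {
  tau <- .first_zero_acf(y)
  z <- y[seq(1, length(y), by = max(1, tau))]
  if (length(z) < 5) return(0)
  q <- stats::quantile(z, c(1 / 3, 2 / 3), names = FALSE, type = 8)
  s <- findInterval(z, q) + 1L
  Tm <- table(factor(s[-length(s)], 1:3), factor(s[-1], 1:3))
  Tm <- Tm / sum(Tm)
  sum(diag(stats::cov(unclass(Tm))))
}

.periodicity_wang <- function(y, th = 0.01) {
  n <- length(y)
  # spline detrend
  tt <- seq_len(n)
  fit <- stats::smooth.spline(tt, y, df = min(10, n - 1))
  r <- y - stats::predict(fit, tt)$y
  a <- .acf_vec(r, min(n - 2, floor(n / 3)))
  # first trough, then first peak after it exceeding the threshold
  trough <- 0
  for (i in 2:(length(a) - 1)) {
    if (trough == 0 && a[i] < a[i - 1] && a[i] < a[i + 1]) trough <- i
    if (trough > 0 && i > trough && a[i] > a[i - 1] && a[i] > a[i + 1] &&
        a[i] > th) return(i)
  }
  0
}

#' Canonical 24-feature summary of one timeseries
#'
#' Computes the 22 canonical dynamical features used for time-series
#' classification (distributional shape, autocorrelation timescales,
#' spectral summaries, symbolic motifs, outlier-inclusion dynamics,
#' forecasting error, fluctuation scaling and periodicity), plus the mean
#' and standard deviation of the raw series. The dynamical block is
#' evaluated on the z-scored series; a constant series returns zeros there
#' (and its mean and SD = 0), never an error. Output order is fixed.
#'
#' @param y Numeric vector (one feature-matrix row, typically 4500 values).
#' @return Named numeric vector of length 24.
#' @export
ts_features <- function(y) {
  stopifnot(is.numeric(y), all(is.finite(y)))
  nm <- c("mode_5", "mode_10", "binarystats_mean_longstretch1",
          "outlier_include_p_mdrmd", "outlier_include_n_mdrmd",
          "f1ecac", "firstmin_ac", "spectral_area_5_1", "spectral_centroid",
          "localsimple_mean3_stderr", "trev_1_num", "histogram_ami_2_5",
          "automutual_fmmi", "pnn40", "binarystats_diff_longstretch0",
          "motifthree_quantile_hh", "localsimple_mean1_tauresrat",
          "embed2_dist_expfit_meandiff", "dfa_prop_r1", "rsrange_prop_r1",
          "transition_matrix_sumdiagcov", "periodicity_wang",
          "mean", "sd")
  out <- stats::setNames(numeric(24), nm)
  out["mean"] <- mean(y)
  out["sd"] <- stats::sd(y)
  z <- .zscore(y)
  if (is.null(z) || length(z) < 20) return(out)
  sp <- .spectrum_rect(z)
  csum <- cumsum(sp$S)
  out["mode_5"] <- .hist_mode(z, 5)
  out["mode_10"] <- .hist_mode(z, 10)
  out["binarystats_mean_longstretch1"] <- .longstretch(z > 0, TRUE)
  out["outlier_include_p_mdrmd"] <- .outlier_include_mdrmd(z)
  out["outlier_include_n_mdrmd"] <- .outlier_include_mdrmd(-z)
  out["f1ecac"] <- .f1ecac(z)
  out["firstmin_ac"] <- .first_min_acf(z)
  out["spectral_area_5_1"] <- csum[max(1, floor(length(sp$S) / 5))] /
    csum[length(csum)]
  out["spectral_centroid"] <- sp$w[which(csum >= csum[length(csum)] / 2)[1]]
  out["localsimple_mean3_stderr"] <- .local_simple_stderr(z, 3)
  out["trev_1_num"] <- mean(diff(z)^3)
  out["histogram_ami_2_5"] <- .ami_even(z, 2, 5)
  out["automutual_fmmi"] <- .gaussian_ami_fmmi(z)
  out["pnn40"] <- mean(abs(diff(z)) > 0.04)
  out["binarystats_diff_longstretch0"] <- .longstretch(diff(z) > 0, FALSE)
  out["motifthree_quantile_hh"] <- .motif_three_hh(z)
  out["localsimple_mean1_tauresrat"] <- .tauresrat(z)
  out["embed2_dist_expfit_meandiff"] <- .embed2_expfit_meandiff(z)
  out["dfa_prop_r1"] <- .fluct_prop_r1(z, "dfa")
  out["rsrange_prop_r1"] <- .fluct_prop_r1(z, "rsrange")
  out["transition_matrix_sumdiagcov"] <- .transition_sumdiagcov(z)
  out["periodicity_wang"] <- .periodicity_wang(z)
  out
}
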