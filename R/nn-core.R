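# Internal neural-network engine for the clip-attention classifier.
#
# The network is built directly on base-R linear algebra: causal 1D
# convolutions are expressed as im2col matrix products (BLAS matmuls), with
# hand-derived backpropagation for every stage. All activations are stored
# feature-major — a batch of B clips of t frames and p features is a
# p x (B*t) matrix with clips occupying contiguous column blocks — so
# per-channel parameters (conv biases, batch-norm scales) broadcast down
# rows via R's column-major recycling without temporary allocations, and a
# whole batch (or all clips of a video at inference) runs through each
# layer as a single matrix product.
#
# Layer order per conv stage (batch-norm placed after the activation):
#   causal conv -> ReLU -> batch norm -> max pool (window 4, stride 4)
# then flatten remaining timesteps, fc(64, ReLU) with dropout before/after,
# sigmoid attention pooling over the clips of each sample, dropout on the
# pooled vector, optional metadata branch, and a 1-unit sigmoid output.

.bn_eps <- 1e-5

# uniform fan-in initialisation, the conventional default for ReLU stacks
.init_mat <- function(nr, nc, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

nn_init <- function(p_features, cfg) {
  f <- cfg$filters; k <- cfg$kernel
  layers <- vector("list", cfg$n_conv)
  p_in <- p_features
  for (l in seq_len(cfg$n_conv)) {
    layers[[l]] <- list(
      W = .init_mat(k * p_in, f, k * p_in), b = numeric(f),
      gamma = rep(1, f), beta = numeric(f),
      rm = numeric(f), rv = rep(1, f))
    p_in <- f
  }
  t_f <- cfg$clip_t / cfg$pool_window^cfg$n_conv
  stopifnot(t_f == round(t_f))
  flat <- as.integer(t_f * f)
  d_out <- cfg$fc_units + if (cfg$use_meta) 2 * cfg$meta_filters else 0
  list(
    conv = layers,
    fc = list(W = .init_mat(flat, cfg$fc_units, flat),
              b = numeric(cfg$fc_units)),
    att = list(W = .init_mat(cfg$fc_units, cfg$fc_units, cfg$fc_units),
               b = numeric(cfg$fc_units),
               u = .init_mat(cfg$fc_units, 1, cfg$fc_units)[, 1]),
    meta = if (cfg$use_meta)
      list(W = .init_mat(1, cfg$meta_filters, 1)[1, ],
           b = numeric(cfg$meta_filters)) else NULL,
    out = list(W = .init_mat(d_out, 1, d_out)[, 1], b = 0),
    flat = flat, t_f = as.integer(t_f))
}

# causal im2col on feature-major input: X is p x (B*t_in); returns
# (k*p) x (B*t_in), zero-padded at each clip's left edge
.im2col_causal <- function(X, B, t_in, k) {
  p <- nrow(X)
  R <- B * t_in
  tt <- rep(seq_len(t_in), B)
  Xcol <- matrix(0, k * p, R)
  for (off in seq_len(k)) {           # input time = out time + off - k
    shift <- off - k
    valid <- which(tt + shift >= 1)
    rows <- ((off - 1) * p + 1):(off * p)
    Xcol[rows, valid] <- X[, valid + shift]
  }
  Xcol
}

.im2col_backward <- function(dXcol, B, t_in, k, p) {
  R <- B * t_in
  tt <- rep(seq_len(t_in), B)
  dX <- matrix(0, p, R)
  for (off in seq_len(k)) {
    shift <- off - k
    valid <- which(tt + shift >= 1)
    rows <- ((off - 1) * p + 1):(off * p)
    src <- valid + shift
    dX[, src] <- dX[, src, drop = FALSE] + dXcol[rows, valid, drop = FALSE]
  }
  dX
}

# max pool over time: columns grouped in windows of `win` within each clip
.pool_forward <- function(Y, win) {
  R <- ncol(Y)
  cur <- Y[, seq(1, R, by = win), drop = FALSE]
  am <- matrix(1L, nrow(cur), ncol(cur))
  for (i in 2:win) {
    Yi <- Y[, seq(i, R, by = win), drop = FALSE]
    upd <- Yi > cur
    am[upd] <- i
    cur[upd] <- Yi[upd]
  }
  list(P = cur, argmax = am)
}

.pool_backward <- function(dP, argmax, win, R, F_) {
  dY <- matrix(0, F_, R)
  for (i in seq_len(win)) {
    mask <- argmax == i
    if (!any(mask)) next
    di <- matrix(0, F_, ncol(dP))
    di[mask] <- dP[mask]
    dY[, seq(i, R, by = win)] <- di
  }
  dY
}

# forward pass over a batch of clips.
#   X: p x (B*t) feature-major; groups: length-B sample assignment (1..G);
#   meta: G x 2 matrix or NULL; training toggles batch statistics + dropout.
# Returns scores (length G), updated params (running BN stats when training)
# and caches for the backward pass.
nn_forward <- function(params, X, B, groups, meta, cfg, training = FALSE) {
  k <- cfg$kernel; win <- cfg$pool_window
  t_in <- cfg$clip_t
  caches <- vector("list", cfg$n_conv)
  A_in <- X
  for (l in seq_len(cfg$n_conv)) {
    ly <- params$conv[[l]]
    Xcol <- .im2col_causal(A_in, B, t_in, k)
    Z <- crossprod(ly$W, Xcol) + ly$b
    A <- Z * (Z > 0)
    if (training) {
      mu <- rowMeans(A)
      va <- pmax(rowMeans(A * A) - mu^2, 0)
      istd <- 1 / sqrt(va + .bn_eps)
      xhat <- (A - mu) * istd
      params$conv[[l]]$rm <- cfg$bn_momentum * ly$rm + (1 - cfg$bn_momentum) * mu
      params$conv[[l]]$rv <- cfg$bn_momentum * ly$rv + (1 - cfg$bn_momentum) * va
    } else {
      istd <- 1 / sqrt(ly$rv + .bn_eps)
      xhat <- (A - ly$rm) * istd
    }
    Y <- xhat * ly$gamma + ly$beta
    pool <- .pool_forward(Y, win)
    caches[[l]] <- list(Xcol = Xcol, relu = Z > 0, xhat = xhat, istd = istd,
                        argmax = pool$argmax, R = ncol(Y), t_in = t_in,
                        p_in = nrow(A_in))
    A_in <- pool$P
    t_in <- t_in / win
  }
  # flatten remaining timesteps per clip: F x (B*t_f) -> (t_f*F) x B
  t_f <- params$t_f
  Mflat <- do.call(rbind, lapply(seq_len(t_f), function(i)
    A_in[, seq(i, B * t_f, by = t_f), drop = FALSE]))
  drop_mask <- function(nr, nc) {
    if (!training || cfg$dropout == 0) return(NULL)
    matrix(stats::rbinom(nr * nc, 1, 1 - cfg$dropout), nr, nc) /
      (1 - cfg$dropout)
  }
  d1 <- drop_mask(params$flat, B)
  M1 <- if (is.null(d1)) Mflat else Mflat * d1
  Hpre <- crossprod(params$fc$W, M1) + params$fc$b
  H <- Hpre * (Hpre > 0)
  d2 <- drop_mask(cfg$fc_units, B)
  m_c <- if (is.null(d2)) H else H * d2                    # fc_units x B
  # sigmoid attention pooling within each sample's group of clips
  U <- tanh(params$att$W %*% m_c + params$att$b)
  alpha <- as.vector(1 / (1 + exp(-crossprod(U, params$att$u))))
  G <- max(groups)
  n_g <- tabulate(groups, G)
  agg <- matrix(0, B, G)
  agg[cbind(seq_len(B), groups)] <- alpha / n_g[groups]
  V <- m_c %*% agg                                         # fc_units x G
  d3 <- drop_mask(cfg$fc_units, G)
  Vd <- if (is.null(d3)) V else V * d3
  if (cfg$use_meta && !is.null(meta)) {
    m8 <- rbind(outer(params$meta$W, meta[, 1]) + params$meta$b,
                outer(params$meta$W, meta[, 2]) + params$meta$b)
    Zfin <- rbind(Vd, m8)
  } else {
    m8 <- NULL
    Zfin <- Vd
  }
  logit <- colSums(Zfin * params$out$W) + params$out$b
  score <- 1 / (1 + exp(-logit))
  list(score = score, params = params,
       cache = list(conv = caches, Mflat = Mflat, M1 = M1, Hpre = Hpre,
                    m_c = m_c, U = U, alpha = alpha, groups = groups,
                    n_g = n_g, V = V, Vd = Vd, meta = meta, m8 = m8,
                    Zfin = Zfin, score = score, B = B,
                    d1 = d1, d2 = d2, d3 = d3, training = training))
}

# backward pass; dlogit has length G (gradient of the loss w.r.t. the
# pre-sigmoid output). Returns parameter gradients and, if want_dX, the
# gradient w.r.t. the input matrix (p x (B*t)).
nn_backward <- function(params, cache, dlogit, cfg, want_dX = FALSE) {
  B <- cache$B; G <- length(dlogit)
  grads <- list(conv = vector("list", cfg$n_conv))
  dZfin <- outer(params$out$W, dlogit)
  grads$out <- list(W = as.vector(cache$Zfin %*% dlogit), b = sum(dlogit))
  dV <- dZfin[seq_len(cfg$fc_units), , drop = FALSE]
  if (!is.null(cache$m8)) {
    dm8 <- dZfin[(cfg$fc_units + 1):nrow(dZfin), , drop = FALSE]
    nf <- cfg$meta_filters
    grads$meta <- list(
      W = as.vector(dm8[1:nf, , drop = FALSE] %*% cache$meta[, 1]) +
        as.vector(dm8[(nf + 1):(2 * nf), , drop = FALSE] %*% cache$meta[, 2]),
      b = rowSums(dm8[1:nf, , drop = FALSE]) +
        rowSums(dm8[(nf + 1):(2 * nf), , drop = FALSE]))
  }
  if (!is.null(cache$d3)) dV <- dV * cache$d3
  # attention: V_g = (1/n_g) sum_{c in g} alpha_c m_c
  w_clip <- 1 / cache$n_g[cache$groups]
  dV_pc <- dV[, cache$groups, drop = FALSE] *
    rep(w_clip, each = cfg$fc_units)
  dalpha <- colSums(dV_pc * cache$m_c)
  dm <- dV_pc * rep(cache$alpha, each = cfg$fc_units)
  dz_att <- dalpha * cache$alpha * (1 - cache$alpha)
  dU <- outer(params$att$u, dz_att) * (1 - cache$U^2)
  grads$att <- list(W = tcrossprod(dU, cache$m_c),
                    b = rowSums(dU),
                    u = as.vector(cache$U %*% dz_att))
  dm <- dm + crossprod(params$att$W, dU)
  if (!is.null(cache$d2)) dm <- dm * cache$d2
  dHpre <- dm * (cache$Hpre > 0)
  grads$fc <- list(W = tcrossprod(cache$M1, dHpre), b = rowSums(dHpre))
  dM1 <- params$fc$W %*% dHpre
  if (!is.null(cache$d1)) dM1 <- dM1 * cache$d1
  # un-flatten to F x (B*t_f)
  t_f <- params$t_f; F_ <- cfg$filters
  dP <- matrix(0, F_, B * t_f)
  for (i in seq_len(t_f)) {
    dP[, seq(i, B * t_f, by = t_f)] <-
      dM1[((i - 1) * F_ + 1):(i * F_), , drop = FALSE]
  }
  win <- cfg$pool_window; k <- cfg$kernel
  for (l in rev(seq_len(cfg$n_conv))) {
    cc <- cache$conv[[l]]
    ly <- params$conv[[l]]
    dY <- .pool_backward(dP, cc$argmax, win, cc$R, F_)
    grads$conv[[l]]$gamma <- rowSums(dY * cc$xhat)
    grads$conv[[l]]$beta <- rowSums(dY)
    dxhat <- dY * ly$gamma
    if (cache$training) {
      m1 <- rowMeans(dxhat)
      m2 <- rowMeans(dxhat * cc$xhat)
      dA <- (dxhat - m1 - cc$xhat * m2) * cc$istd
    } else {
      dA <- dxhat * cc$istd
    }
    dZ <- dA * cc$relu
    grads$conv[[l]]$W <- tcrossprod(cc$Xcol, dZ)
    grads$conv[[l]]$b <- rowSums(dZ)
    if (l > 1 || want_dX) {
      dXcol <- ly$W %*% dZ
      dP <- .im2col_backward(dXcol, B, cc$t_in, k, cc$p_in)
    } else {
      dP <- NULL
    }
  }
  list(grads = grads, dX = dP)
}

# SGD with Nesterov momentum; l2 applied to weight kernels only (not biases,
# not batch-norm parameters)
nn_update <- function(params, grads, state, cfg) {
  lr <- cfg$lr; mu <- cfg$momentum
  upd <- function(key, w, g, is_kernel) {
    if (is_kernel && cfg$l2 > 0) g <- g + 2 * cfg$l2 * w
    v <- state[[key]]
    if (is.null(v)) v <- 0 * g
    v <- mu * v - lr * g
    state[[key]] <<- v
    w + mu * v - lr * g   # Nesterov look-ahead step
  }
  for (l in seq_along(params$conv)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      params$conv[[l]][[nm]] <- upd(paste0("conv", l, ".", nm),
                                    params$conv[[l]][[nm]],
                                    grads$conv[[l]][[nm]],
                                    is_kernel = (nm == "W"))
    }
  }
  for (nm in c("W", "b"))
    params$fc[[nm]] <- upd(paste0("fc.", nm), params$fc[[nm]],
                           grads$fc[[nm]], nm == "W")
  for (nm in c("W", "b", "u"))
    params$att[[nm]] <- upd(paste0("att.", nm), params$att[[nm]],
                            grads$att[[nm]], nm %in% c("W", "u"))
  if (!is.null(params$meta) && !is.null(grads$meta)) {
    for (nm in c("W", "b"))
      params$meta[[nm]] <- upd(paste0("meta.", nm), params$meta[[nm]],
                               grads$meta[[nm]], nm == "W")
  }
  for (nm in c("W", "b"))
    params$out[[nm]] <- upd(paste0("out.", nm), params$out[[nm]],
                            grads$out[[nm]], nm == "W")
  list(params = params, state = state)
}
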