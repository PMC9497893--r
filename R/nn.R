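# Minimal neural-network primitives on N x H x W x C numeric arrays.
# Forward and backward passes are hand-written; all heavy lifting is BLAS
# matrix products.  Double precision throughout.

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.99

new_bn <- function(c) list(gamma = rep(1, c), beta = rep(0, c))
new_bn_stats <- function(c) list(mean = rep(0, c), var = rep(1, c))

# Batch normalisation over the N, H, W axes.
# Returns y plus the batch statistics needed for backward / running update.
bn_fwd <- function(x, bn, rs, training) {
  d <- dim(x); m <- prod(d[1:3])
  fw <- bn_fwd_fused_cpp(x, m, bn$gamma, bn$beta, rs$mean, rs$var,
                         training, BN_EPS)
  y <- fw$y
  dim(y) <- d
  list(y = y, xhat = fw$xhat, istd = fw$istd, mu = fw$mu, var = fw$var)
}

bn_update_stats <- function(rs, fw) {
  rs$mean <- BN_MOMENTUM * rs$mean + (1 - BN_MOMENTUM) * fw$mu
  rs$var <- BN_MOMENTUM * rs$var + (1 - BN_MOMENTUM) * fw$var
  rs
}

bn_bwd <- function(dy, bn, fw, training) {
  d <- dim(dy); m <- prod(d[1:3])
  xh <- fw$xhat
  dim(xh) <- c(m, length(fw$istd))
  dym <- dy
  dim(dym) <- c(m, length(fw$istd))
  g <- bn_bwd_cpp(dym, xh, bn$gamma * fw$istd, training)
  dx <- g$dx
  dim(dx) <- d
  list(dx = dx, dgamma = g$dgamma, dbeta = g$dbeta)
}

# TF-style SAME padding sizes for one spatial axis
same_pad <- function(n, k, s) {
  out <- ceiling(n / s)
  tot <- max((out - 1L) * s + k - n, 0L)
  c(beg = tot %/% 2L, end = tot - tot %/% 2L)
}

pad_nhwc <- function(x, ph, pw) {
  if (all(c(ph, pw) == 0L)) return(x)
  d <- dim(x)
  out <- array(0, c(d[1L], d[2L] + sum(ph), d[3L] + sum(pw), d[4L]))
  out[, ph[1L] + seq_len(d[2L]), pw[1L] + seq_len(d[3L]), ] <- x
  out
}

# Full convolution via im2col; used only for the small stem kernel.
# w: array (k, k, ic, f)
conv2d_fwd <- function(x, w, stride) {
  d <- dim(x); k <- dim(w)[1L]; ic <- d[4L]; f <- dim(w)[4L]
  ph <- same_pad(d[2L], k, stride); pw <- same_pad(d[3L], k, stride)
  xp <- pad_nhwc(x, ph, pw)
  ho <- ceiling(d[2L] / stride); wo <- ceiling(d[3L] / stride)
  cols <- array(0, c(d[1L], ho, wo, k * k * ic))
  slot <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    ii <- di + stride * (seq_len(ho) - 1L)
    jj <- dj + stride * (seq_len(wo) - 1L)
    cols[, , , slot * ic + seq_len(ic)] <- xp[, ii, jj, , drop = FALSE]
    slot <- slot + 1L
  }
  wm <- matrix(0, k * k * ic, f)
  slot <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    wm[slot * ic + seq_len(ic), ] <- w[di, dj, , ]
    slot <- slot + 1L
  }
  y <- matrix(cols, ncol = k * k * ic) %*% wm
  dim(y) <- c(d[1L], ho, wo, f)
  list(y = y, cols = cols, wm = wm, xdim = d, pads = list(ph = ph, pw = pw))
}

conv2d_bwd <- function(dy, w, fw, stride) {
  k <- dim(w)[1L]; ic <- dim(w)[3L]; f <- dim(w)[4L]
  dyo <- dim(dy)
  dym <- matrix(dy, ncol = f)
  colm <- matrix(fw$cols, ncol = k * k * ic)
  dwm <- crossprod(colm, dym)
  dcols <- dym %*% t(fw$wm)
  dim(dcols) <- dim(fw$cols)
  d <- fw$xdim; ph <- fw$pads$ph; pw <- fw$pads$pw
  dxp <- array(0, c(d[1L], d[2L] + sum(ph), d[3L] + sum(pw), ic))
  ho <- dyo[2L]; wo <- dyo[3L]
  slot <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    ii <- di + stride * (seq_len(ho) - 1L)
    jj <- dj + stride * (seq_len(wo) - 1L)
    dxp[, ii, jj, ] <- dxp[, ii, jj, , drop = FALSE] +
      dcols[, , , slot * ic + seq_len(ic), drop = FALSE]
    slot <- slot + 1L
  }
  dx <- dxp[, ph[1L] + seq_len(d[2L]), pw[1L] + seq_len(d[3L]), , drop = FALSE]
  dw <- array(0, dim(w))
  slot <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    dw[di, dj, , ] <- dwm[slot * ic + seq_len(ic), ]
    slot <- slot + 1L
  }
  list(dx = dx, dw = dw)
}

# Depthwise convolution, SAME padding.  w: array (k, k, c)
dwconv_fwd <- function(x, w, stride) {
  d <- dim(x); k <- dim(w)[1L]; cc <- d[4L]
  ph <- same_pad(d[2L], k, stride); pw <- same_pad(d[3L], k, stride)
  xp <- pad_nhwc(x, ph, pw)
  ho <- ceiling(d[2L] / stride); wo <- ceiling(d[3L] / stride)
  y <- dw_fwd_cpp(xp, dim(xp), w, k, stride, ho, wo)
  dim(y) <- c(d[1L], ho, wo, cc)
  list(y = y, xp = xp, pads = list(ph = ph, pw = pw), xdim = d)
}

dwconv_bwd <- function(dy, w, fw, stride) {
  k <- dim(w)[1L]
  d <- fw$xdim; ho <- dim(dy)[2L]; wo <- dim(dy)[3L]
  g <- dw_bwd_cpp(dy, fw$xp, dim(fw$xp), w, k, stride, ho, wo)
  dxp <- g$dxp; dim(dxp) <- dim(fw$xp)
  dw <- g$dw; dim(dw) <- dim(w)
  ph <- fw$pads$ph; pw <- fw$pads$pw
  dx <- dxp[, ph[1L] + seq_len(d[2L]), pw[1L] + seq_len(d[3L]), , drop = FALSE]
  list(dx = dx, dw = dw)
}

# Plain pointwise conv as a layer (w: f x ic matrix, optional bias)
pwconv_fwd <- function(x, w, b = NULL) {
  y <- pointwise_conv(x, w)
  if (!is.null(b)) {
    d <- dim(y)
    y <- y + rep(b, each = prod(d[1:3]))
  }
  y
}

pwconv_bwd <- function(x, w, dy, has_bias = FALSE) {
  d <- dim(x)
  xm <- matrix(x, ncol = d[4L])
  dym <- matrix(dy, ncol = nrow(w))
  dw <- crossprod(dym, xm)
  dx <- dym %*% w
  dim(dx) <- d
  out <- list(dx = dx, dw = dw)
  if (has_bias) out$db <- colSums(dym)
  out
}

# Global average pooling: N x H x W x C -> N x 1 x 1 x C
# The flattened (N, H*W, C) layout groups rows by image via rep(1:N, H*W).
gap_fwd <- function(x) {
  d <- dim(x)
  xm <- matrix(x, ncol = d[4L])
  y <- rowsum(xm, rep(seq_len(d[1L]), d[2L] * d[3L])) / (d[2L] * d[3L])
  array(y, c(d[1L], 1L, 1L, d[4L]))
}

gap_bwd <- function(dy, xdim) {
  scale <- 1 / (xdim[2L] * xdim[3L])
  dyv <- matrix(dy, nrow = xdim[1L]) * scale  # N x C
  big <- dyv[rep(seq_len(xdim[1L]), xdim[2L] * xdim[3L]), , drop = FALSE]
  dim(big) <- xdim
  big
}

# Broadcast-multiply x (N,H,W,C) by a per-image channel gate s (N,1,1,C)
scale_bc <- function(x, s) {
  d <- dim(x)
  sm <- matrix(s, nrow = d[1L])
  big <- sm[rep(seq_len(d[1L]), d[2L] * d[3L]), , drop = FALSE]
  dim(big) <- d
  x * big
}

# gradient of sum over H,W: collapse (N,H,W,C) to (N,1,1,C)
collapse_hw <- function(t) {
  d <- dim(t)
  y <- rowsum(matrix(t, ncol = d[4L]), rep(seq_len(d[1L]), d[2L] * d[3L]))
  array(y, c(d[1L], 1L, 1L, d[4L]))
}

sigmoid <- function(x) {
  y <- sigmoid_cpp(x)
  if (!is.null(dim(x))) dim(y) <- dim(x)
  y
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# cross-entropy loss with integer labels (1-based); returns loss and dlogits
softmax_xent <- function(logits, labels) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / n, probs = p)
}
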