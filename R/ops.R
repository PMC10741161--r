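# Low-level differentiable operations. Each *_fwd returns the output plus the
# cache its matching *_bwd needs. Conventions: single images are H x W x C
# arrays; batches are H x W x C x B arrays; token sequences are L x D matrices.
# All backwards are validated against central finite differences in the tests.

## ---- initialisation -------------------------------------------------------

# Truncated normal on (-2 sd, 2 sd) via inverse-CDF sampling: deterministic
# under set.seed (no rejection loop).
trunc_normal <- function(n, std = 0.02) {
  lo <- stats::pnorm(-2)
  hi <- stats::pnorm(2)
  stats::qnorm(stats::runif(n, lo, hi)) * std
}

tn_array <- function(dims, std = 0.02) {
  array(trunc_normal(prod(dims), std), dim = dims)
}

tn_matrix <- function(nr, nc, std = 0.02) {
  matrix(trunc_normal(nr * nc, std), nr, nc)
}

## ---- elementwise ----------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# Exact GELU: x * Phi(x).
gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Numerically stable row softmax of a matrix.
row_softmax <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# Backward of row softmax: given A = softmax(Z) and dA, return dZ.
row_softmax_bwd <- function(dA, A) {
  A * (dA - rowSums(dA * A))
}

# Row log-softmax (for cross-entropy).
row_log_softmax <- function(x) {
  m <- apply(x, 1L, max)
  s <- x - m
  s - log(rowSums(exp(s)))
}

## ---- linear ---------------------------------------------------------------

# y = x %*% W + b, x: n x in, W: in x out, b: length out.
linear_fwd <- function(x, W, b) {
  y <- x %*% W
  y <- sweep(y, 2L, b, "+")
  list(out = y, x = x)
}

linear_bwd <- function(dy, cache, W) {
  list(dx = dy %*% t(W),
       dW = crossprod(cache$x, dy),
       db = colSums(dy))
}

## ---- layer norm (per row) -------------------------------------------------

LN_EPS <- 1e-5
BN_EPS <- 1e-5

layernorm_fwd <- function(x, gamma, beta) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = out, xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2L, gamma, "*")
  # per-row: dx = inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx,
       dgamma = colSums(dy * xhat),
       dbeta = colSums(dy))
}

## ---- 2-D convolution (im2col) ---------------------------------------------

# Build the im2col matrix of one image: rows = output positions (row index
# fastest, matching R's column-major matrix layout), columns ordered with the
# kernel row index fastest, then kernel column, then input channel -- the same
# order as as.vector() of a kh x kw x cin x cout weight array.
im2col <- function(xp, kh, kw, cin, stride, hout, wout) {
  cols <- matrix(0, hout * wout, kh * kw * cin)
  idx <- 0L
  for (c in seq_len(cin)) {
    for (kj in seq_len(kw)) {
      for (ki in seq_len(kh)) {
        idx <- idx + 1L
        cols[, idx] <- xp[seq.int(ki, by = stride, length.out = hout),
                          seq.int(kj, by = stride, length.out = wout), c]
      }
    }
  }
  cols
}

pad_hw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  xp
}

# x: H x W x Cin, w: kh x kw x Cin x Cout, b: length Cout.
conv2d_fwd <- function(x, w, b, stride = 1L, pad = 0L) {
  d <- dim(x)
  dw <- dim(w)
  if (d[3] != dw[3]) {
    stop(sprintf("conv2d: input has %d channels but kernel expects %d",
                 d[3], dw[3]))
  }
  hout <- (d[1] + 2 * pad - dw[1]) %/% stride + 1L
  wout <- (d[2] + 2 * pad - dw[2]) %/% stride + 1L
  xp <- pad_hw(x, pad)
  cols <- im2col(xp, dw[1], dw[2], dw[3], stride, hout, wout)
  wmat <- matrix(w, ncol = dw[4])
  y <- cols %*% wmat
  y <- sweep(y, 2L, b, "+")
  list(out = array(y, c(hout, wout, dw[4])),
       cols = cols, in_dim = d, pad = pad, stride = stride)
}

conv2d_bwd <- function(dy, cache, w) {
  dw_dim <- dim(w)
  dout <- dim(dy)
  hout <- dout[1]; wout <- dout[2]
  dymat <- matrix(dy, ncol = dw_dim[4])
  wmat <- matrix(w, ncol = dw_dim[4])
  dW <- array(crossprod(cache$cols, dymat), dim = dw_dim)
  db <- colSums(dymat)
  dcols <- tcrossprod(dymat, wmat)
  d <- cache$in_dim
  p <- cache$pad
  stride <- cache$stride
  dxp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  idx <- 0L
  for (c in seq_len(dw_dim[3])) {
    for (kj in seq_len(dw_dim[2])) {
      for (ki in seq_len(dw_dim[1])) {
        idx <- idx + 1L
        ri <- seq.int(ki, by = stride, length.out = hout)
        ci <- seq.int(kj, by = stride, length.out = wout)
        dxp[ri, ci, c] <- dxp[ri, ci, c] + matrix(dcols[, idx], hout, wout)
      }
    }
  }
  dx <- if (p > 0) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , drop = FALSE]
        else dxp
  list(dx = dx, dW = dW, db = db)
}

## ---- bilinear resize ------------------------------------------------------

# Half-pixel-centre source coordinates (the torchvision align_corners = FALSE
# convention), clamped to the valid range.
bilinear_coeffs <- function(n_in, n_out) {
  s <- n_in / n_out
  src <- (seq_len(n_out) - 0.5) * s - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  lo <- floor(src)
  w_hi <- src - lo
  i0 <- as.integer(lo) + 1L
  i1 <- pmin(i0 + 1L, n_in)
  list(i0 = i0, i1 = i1, w0 = 1 - w_hi, w1 = w_hi)
}

# Dense interpolation matrix (n_out x n_in); used where the exact transpose is
# needed for backprop (the stem's upsample, where sizes are small).
bilinear_matrix <- function(n_in, n_out) {
  cf <- bilinear_coeffs(n_in, n_out)
  M <- matrix(0, n_out, n_in)
  M[cbind(seq_len(n_out), cf$i0)] <- M[cbind(seq_len(n_out), cf$i0)] + cf$w0
  M[cbind(seq_len(n_out), cf$i1)] <- M[cbind(seq_len(n_out), cf$i1)] + cf$w1
  M
}

# Gather-based separable bilinear resize of an H x W x C array; fast path for
# data transforms (no gradient needed there).
resize_bilinear <- function(x, out_h, out_w) {
  d <- dim(x)
  rc <- bilinear_coeffs(d[1], out_h)
  cc <- bilinear_coeffs(d[2], out_w)
  out <- array(0, c(out_h, out_w, d[3]))
  for (c in seq_len(d[3])) {
    ch <- x[, , c]
    rows <- ch[rc$i0, , drop = FALSE] * rc$w0 +
            ch[rc$i1, , drop = FALSE] * rc$w1
    out[, , c] <- rows[, cc$i0, drop = FALSE] *
                    rep(cc$w0, each = out_h) +
                  rows[, cc$i1, drop = FALSE] *
                    rep(cc$w1, each = out_h)
  }
  out
}

## ---- dropout --------------------------------------------------------------

# Inverted dropout; consumes the R RNG stream when active.
dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) {
    return(list(out = x, mask = NULL))
  }
  mask <- (matrix(stats::runif(length(x)), nrow(x)) >= p) / (1 - p)
  list(out = x * mask, mask = mask)
}

dropout_bwd <- function(dy, cache) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}
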