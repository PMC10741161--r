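# Residual convolutional stem. Main path: 3x3 conv (stride s, 3 -> mid) ->
# BN -> ReLU -> 3x3 conv (mid -> 3) -> BN -> bilinear upsample xs back to the
# input resolution. Shortcut: 1x1 conv (3 -> 3) -> BN. Output =
# ReLU(main + shortcut), same shape as the input, so patch tokens can be taken
# from it exactly as from the raw image.
#
# Internals keep batched activations as (H*W*B) x C matrices with the spatial
# index fastest, then the batch index: the layout the batched im2col emits,
# the batch-norm layers consume directly and array(m, c(H, W, B, C))
# reconstitutes without copying games.

stem_init <- function(config) {
  C <- config$in_channels
  mid <- config$stem_mid_channels
  list(
    conv1_w = tn_array(c(3, 3, C, mid)),
    conv1_b = numeric(mid),
    bn1_gamma = rep(1, mid), bn1_beta = numeric(mid),
    conv2_w = tn_array(c(3, 3, mid, C)),
    conv2_b = numeric(C),
    bn2_gamma = rep(1, C), bn2_beta = numeric(C),
    conv3_w = tn_array(c(1, 1, C, C)),
    conv3_b = numeric(C),
    bn3_gamma = rep(1, C), bn3_beta = numeric(C)
  )
}

stem_buffers_init <- function(config) {
  C <- config$in_channels
  mid <- config$stem_mid_channels
  list(bn1 = list(mean = numeric(mid), var = rep(1, mid)),
       bn2 = list(mean = numeric(C), var = rep(1, C)),
       bn3 = list(mean = numeric(C), var = rep(1, C)))
}

## ---- batched conv on (H, W, B, C) arrays ------------------------------------

pad_hwbc <- function(x, p) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  xp
}

# x: H x W x B x Cin array; returns out as (hout*wout*B) x cout matrix.
# Shift-and-matmul formulation: one (hout*wout*B) x cin block slice and one
# matmul per kernel tap -- kh*kw big BLAS calls instead of kh*kw*cin column
# gathers.
conv2d_batch_fwd <- function(x, w, b, stride = 1L, pad = 0L) {
  d <- dim(x)
  dw <- dim(w)
  hout <- (d[1] + 2 * pad - dw[1]) %/% stride + 1L
  wout <- (d[2] + 2 * pad - dw[2]) %/% stride + 1L
  xp <- if (pad > 0) pad_hwbc(x, pad) else x
  B <- d[3]
  n <- hout * wout * B
  y <- matrix(rep(b, each = n), n, dw[4])
  taps <- vector("list", dw[1] * dw[2])
  t_ix <- 0L
  for (kj in seq_len(dw[2])) {
    for (ki in seq_len(dw[1])) {
      Xs <- xp[seq.int(ki, by = stride, length.out = hout),
               seq.int(kj, by = stride, length.out = wout), , , drop = FALSE]
      dim(Xs) <- c(n, dw[3])
      y <- y + Xs %*% matrix(w[ki, kj, , ], dw[3], dw[4])
      t_ix <- t_ix + 1L
      taps[[t_ix]] <- Xs
    }
  }
  list(out = y, taps = taps, in_dim = d, pad = pad, stride = stride,
       hout = hout, wout = wout)
}

# dy: (hout*wout*B) x cout matrix. dx is returned as an (H*W*B) x Cin matrix
# (same row layout as the forward activations); computed as a transposed
# convolution (gather, stride-1 convs only) and skipped with need_dx = FALSE
# (the stem's first conv sits on the raw image, whose gradient nothing
# consumes).
conv2d_batch_bwd <- function(dy, cache, w, need_dx = TRUE) {
  dw_dim <- dim(w)
  d <- cache$in_dim
  db <- colSums(dy)
  dW <- array(0, dim = dw_dim)
  t_ix <- 0L
  for (kj in seq_len(dw_dim[2])) {
    for (ki in seq_len(dw_dim[1])) {
      t_ix <- t_ix + 1L
      dW[ki, kj, , ] <- crossprod(cache$taps[[t_ix]], dy)
    }
  }
  dx <- NULL
  if (need_dx) {
    if (cache$stride != 1L) {
      stop("input gradient implemented for stride-1 convolutions only")
    }
    dy_arr <- dy
    dim(dy_arr) <- c(cache$hout, cache$wout, d[3], dw_dim[4])
    # rotate the kernel 180 degrees and swap in/out channels
    wrot <- aperm(w[rev(seq_len(dw_dim[1])), rev(seq_len(dw_dim[2])), , ,
                    drop = FALSE], c(1, 2, 4, 3))
    dx <- conv2d_batch_fwd(dy_arr, wrot, numeric(dw_dim[3]), stride = 1L,
                           pad = dw_dim[1] - 1L - cache$pad)$out
  }
  list(dx = dx, dW = dW, db = db)
}

## ---- batch norm on (N x C) matrices -----------------------------------------

bn_mat_fwd <- function(xm, gamma, beta, running, training, momentum = 0.1) {
  if (training) {
    n <- nrow(xm)
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    v <- colMeans(xc * xc)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var +
      momentum * v * n / max(n - 1, 1)
  } else {
    mu <- running$mean
    xc <- sweep(xm, 2L, mu)
    v <- running$var
  }
  inv <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(xc, 2L, inv, "*")
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = out, xhat = xhat, inv = inv, running = running,
       training = training)
}

bn_mat_bwd <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  if (cache$training) {
    dxhat <- sweep(dy, 2L, gamma, "*")
    t1 <- sweep(dxhat, 2L, colMeans(dxhat))
    t2 <- sweep(xhat, 2L, colMeans(dxhat * xhat), "*")
    dx <- sweep(t1 - t2, 2L, cache$inv, "*")
  } else {
    dx <- sweep(sweep(dy, 2L, gamma, "*"), 2L, cache$inv, "*")
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- separable bilinear upsample on (h x w x B x C) -------------------------

# out = Ru %*% X %*% t(Cu) applied to every (b, c) slice via two big matmuls.
upsample_batch <- function(x, Ru, Cu) {
  d <- dim(x)  # h2, w2, B, C
  H <- nrow(Ru); W <- nrow(Cu)
  y <- Ru %*% matrix(x, d[1])                    # H x (w2*B*C)
  y <- array(y, c(H, d[2], d[3], d[4]))
  y <- aperm(y, c(2, 1, 3, 4))                   # w2 x H x B x C
  y <- Cu %*% matrix(y, d[2])                    # W x (H*B*C)
  aperm(array(y, c(W, H, d[3], d[4])), c(2, 1, 3, 4))
}

## ---- stem forward/backward --------------------------------------------------

# x: H x W x B x C batch. Returns out (same dims), cache, updated buffers.
stem_batch_fwd <- function(x, p, buffers, config, training = FALSE) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; B <- d[3]; C <- d[4]
  s <- config$stem_stride
  if (H %% s != 0 || W %% s != 0) {
    stop(sprintf("stem: input %dx%d not divisible by stem_stride %d", H, W, s))
  }
  if (C != config$in_channels) {
    stop(sprintf("stem: expected %d channels, got %d", config$in_channels, C))
  }
  h2 <- H %/% s; w2 <- W %/% s

  c1 <- conv2d_batch_fwd(x, p$conv1_w, p$conv1_b, stride = s, pad = 1L)
  if (c1$hout != h2 || c1$wout != w2) {
    stop(sprintf(
      "stem: main branch produced %dx%d but %dx%d is required for upsample",
      c1$hout, c1$wout, h2, w2))
  }
  bn1 <- bn_mat_fwd(c1$out, p$bn1_gamma, p$bn1_beta, buffers$bn1, training)
  z1 <- pmax(bn1$out, 0)

  mid <- config$stem_mid_channels
  c2 <- conv2d_batch_fwd(array(z1, c(h2, w2, B, mid)),
                         p$conv2_w, p$conv2_b, stride = 1L, pad = 1L)
  bn2 <- bn_mat_fwd(c2$out, p$bn2_gamma, p$bn2_beta, buffers$bn2, training)
  Ru <- bilinear_matrix(h2, H)
  Cu <- bilinear_matrix(w2, W)
  z2 <- upsample_batch(array(bn2$out, c(h2, w2, B, C)), Ru, Cu)
  z2 <- matrix(z2, ncol = C)                     # (H*W*B) x C

  xm <- matrix(x, ncol = C)
  w3 <- matrix(p$conv3_w, C, C)
  sc <- sweep(xm %*% w3, 2L, p$conv3_b, "+")
  bn3 <- bn_mat_fwd(sc, p$bn3_gamma, p$bn3_beta, buffers$bn3, training)

  pre_relu <- z2 + bn3$out
  out <- pmax(pre_relu, 0)
  dim(out) <- c(H, W, B, C)

  buffers$bn1 <- bn1$running
  buffers$bn2 <- bn2$running
  buffers$bn3 <- bn3$running
  list(out = out, buffers = buffers,
       cache = list(c1 = c1, bn1 = bn1, z1 = z1, c2 = c2, bn2 = bn2,
                    Ru = Ru, Cu = Cu, bn3 = bn3, xm = xm,
                    pre_relu = pre_relu, dims = d, h2 = h2, w2 = w2))
}

# dout: H x W x B x C. Returns the stem parameter grads (the image gradient
# is never consumed and is not formed).
stem_batch_bwd <- function(dout, cache, p) {
  d <- cache$dims
  H <- d[1]; W <- d[2]; B <- d[3]; C <- d[4]
  gm <- matrix(dout, ncol = C) * (cache$pre_relu > 0)

  # shortcut
  bn3b <- bn_mat_bwd(gm, cache$bn3, p$bn3_gamma)
  dconv3_w <- crossprod(cache$xm, bn3b$dx)
  dconv3_b <- colSums(bn3b$dx)

  # main: upsample^T -> bn2 -> conv2 -> relu -> bn1 -> conv1
  h2 <- cache$h2; w2 <- cache$w2
  dz2 <- upsample_batch(array(gm, c(H, W, B, C)),
                        t(cache$Ru), t(cache$Cu))
  bn2b <- bn_mat_bwd(matrix(dz2, ncol = C), cache$bn2, p$bn2_gamma)
  c2b <- conv2d_batch_bwd(bn2b$dx, cache$c2, p$conv2_w)
  dz1 <- c2b$dx * (cache$z1 > 0)
  bn1b <- bn_mat_bwd(dz1, cache$bn1, p$bn1_gamma)
  # the stem is the first block: the image gradient is never consumed, so the
  # input gradient of conv1 (and hence of the whole stem) is not materialised
  c1b <- conv2d_batch_bwd(bn1b$dx, cache$c1, p$conv1_w, need_dx = FALSE)
  list(dx = NULL,
       grads = list(conv1_w = c1b$dW, conv1_b = c1b$db,
                    bn1_gamma = bn1b$dgamma, bn1_beta = bn1b$dbeta,
                    conv2_w = c2b$dW, conv2_b = c2b$db,
                    bn2_gamma = bn2b$dgamma, bn2_beta = bn2b$dbeta,
                    conv3_w = array(dconv3_w, dim(p$conv3_w)),
                    conv3_b = dconv3_b,
                    bn3_gamma = bn3b$dgamma, bn3_beta = bn3b$dbeta))
}

#' Residual stem forward pass
#'
#' Applies the residual convolutional stem to a single image: a strided 3x3
#' convolution with batch norm and ReLU, a second 3x3 convolution with batch
#' norm followed by bilinear upsampling back to the input resolution, plus a
#' 1x1-convolution shortcut with batch norm; the two paths are summed and
#' passed through a final ReLU. Channels are preserved (3 in, 3 out) so the
#' output can be patchified exactly like the raw image.
#'
#' @param image An `H x W x 3` numeric array, `H` and `W` divisible by the
#'   configured stem stride.
#' @param model A `flater_model` (provides parameters, normalisation buffers
#'   and configuration).
#' @param training Logical; use batch statistics (`TRUE`) or running
#'   statistics (`FALSE`, default) in the batch-norm layers.
#' @return An `H x W x 3` numeric array of stem features.
#' @export
stem_forward <- function(image, model, training = FALSE) {
  stopifnot(inherits(model, "flater_model"))
  if (is.null(model$params$stem)) {
    stop(sprintf("model variant '%s' has no residual stem", model$variant))
  }
  d <- dim(image)
  if (length(d) != 3 || d[3] != model$config$in_channels) {
    stop(sprintf("expected an H x W x %d image", model$config$in_channels))
  }
  xb <- aperm(array(image, c(d, 1L)), c(1, 2, 4, 3))
  res <- stem_batch_fwd(xb, model$params$stem, model$buffers, model$config,
                        training = training)
  res$out[, , 1, , drop = TRUE]
}
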