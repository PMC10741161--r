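# Shared fixtures and independent brute-force oracles. The oracles are written
# as plain nested loops / direct formulas, independent of the package's
# vectorised implementations.

tiny_config <- function(...) {
  flater_config(image_size = 8, patch_size = 4, embed_dim = 12,
                stem_mid_channels = 5, depth = 2, num_heads = 3,
                mlp_ratio = 2, ...)
}

micro_config <- function(...) {
  # smallest trainable geometry: 32x32 input, 4 patches + CLS, 12-dim tokens
  flater_config(image_size = 32, patch_size = 16, embed_dim = 12,
                stem_mid_channels = 4, depth = 1, num_heads = 2,
                mlp_ratio = 2, ...)
}

smoke_config <- function(...) {
  flater_config(image_size = 64, patch_size = 16, embed_dim = 48,
                stem_mid_channels = 32, depth = 2, num_heads = 4, ...)
}

desk_dataset <- function(train = c(20L, 7L, 7L, 6L),
                         validation = c(6L, 2L, 2L, 2L),
                         test = c(6L, 2L, 2L, 2L), seed = 42) {
  synthesize_dataset(
    synthetic_spec(preset = "desk"),
    data.frame(class = flater_classes(), train = train,
               validation = validation, test = test),
    seed = seed)
}

rand_image <- function(h, w, c = 3, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(h * w * c), c(h, w, c))
}

# Direct-definition 2-D convolution with zero padding.
naive_conv2d <- function(x, w, b, stride = 1, pad = 0) {
  d <- dim(x); dw <- dim(w)
  hout <- (d[1] + 2 * pad - dw[1]) %/% stride + 1
  wout <- (d[2] + 2 * pad - dw[2]) %/% stride + 1
  out <- array(0, c(hout, wout, dw[4]))
  for (oc in seq_len(dw[4])) {
    for (i in seq_len(hout)) {
      for (j in seq_len(wout)) {
        acc <- b[oc]
        for (ki in seq_len(dw[1])) {
          for (kj in seq_len(dw[2])) {
            si <- (i - 1) * stride + ki - pad
            sj <- (j - 1) * stride + kj - pad
            if (si >= 1 && si <= d[1] && sj >= 1 && sj <= d[2]) {
              for (ic in seq_len(dw[3])) {
                acc <- acc + x[si, sj, ic] * w[ki, kj, ic, oc]
              }
            }
          }
        }
        out[i, j, oc] <- acc
      }
    }
  }
  out
}

# Direct-definition bilinear interpolation with half-pixel centres.
naive_bilinear <- function(x, out_h, out_w) {
  d <- dim(x)
  out <- array(0, c(out_h, out_w, d[3]))
  for (c in seq_len(d[3])) {
    for (i in seq_len(out_h)) {
      for (j in seq_len(out_w)) {
        sy <- min(max((i - 0.5) * d[1] / out_h - 0.5, 0), d[1] - 1)
        sx <- min(max((j - 0.5) * d[2] / out_w - 0.5, 0), d[2] - 1)
        y0 <- floor(sy); x0 <- floor(sx)
        y1 <- min(y0 + 1, d[1] - 1); x1 <- min(x0 + 1, d[2] - 1)
        fy <- sy - y0; fx <- sx - x0
        out[i, j, c] <-
          x[y0 + 1, x0 + 1, c] * (1 - fy) * (1 - fx) +
          x[y1 + 1, x0 + 1, c] * fy * (1 - fx) +
          x[y0 + 1, x1 + 1, c] * (1 - fy) * fx +
          x[y1 + 1, x1 + 1, c] * fy * fx
      }
    }
  }
  out
}

# Eval-mode batch norm from running statistics, plain arithmetic.
naive_bn_eval <- function(x, gamma, beta, mean, var, eps = 1e-5) {
  out <- x
  for (c in seq_len(dim(x)[3])) {
    out[, , c] <- (x[, , c] - mean[c]) / sqrt(var[c] + eps) * gamma[c] +
      beta[c]
  }
  out
}

# Hand-rolled single-layer pre-norm encoder for an L x D token matrix.
naive_encoder_layer <- function(x, p, num_heads) {
  ln <- function(v, g, b) {
    mu <- mean(v); sd <- sqrt(mean((v - mu)^2) + 1e-5)
    (v - mu) / sd * g + b
  }
  L <- nrow(x); D <- ncol(x); dh <- D / num_heads
  a <- t(apply(x, 1, ln, g = p$ln1_gamma, b = p$ln1_beta))
  Q <- a %*% p$attn$Wq + matrix(p$attn$bq, L, D, byrow = TRUE)
  K <- a %*% p$attn$Wk + matrix(p$attn$bk, L, D, byrow = TRUE)
  V <- a %*% p$attn$Wv + matrix(p$attn$bv, L, D, byrow = TRUE)
  O <- matrix(0, L, D)
  for (h in seq_len(num_heads)) {
    cols <- (h - 1) * dh + seq_len(dh)
    for (i in seq_len(L)) {
      s <- numeric(L)
      for (j in seq_len(L)) {
        s[j] <- sum(Q[i, cols] * K[j, cols]) / sqrt(dh)
      }
      w <- exp(s - max(s)); w <- w / sum(w)
      for (j in seq_len(L)) O[i, cols] <- O[i, cols] + w[j] * V[j, cols]
    }
  }
  x2 <- x + O %*% p$attn$Wo + matrix(p$attn$bo, L, D, byrow = TRUE)
  bmat <- t(apply(x2, 1, ln, g = p$ln2_gamma, b = p$ln2_beta))
  h1 <- bmat %*% p$mlp$W1 + matrix(p$mlp$b1, L, ncol(p$mlp$W1), byrow = TRUE)
  act <- h1 * pnorm(h1)
  x2 + act %*% p$mlp$W2 + matrix(p$mlp$b2, L, D, byrow = TRUE)
}

# Closed-form parameter ledger.
ledger_layer_params <- function(D, mlp_ratio) {
  h <- mlp_ratio * D
  4 * D^2 + 2 * D * h + 9 * D + h
}

ledger_total_params <- function(cfg, variant = "full") {
  D <- cfg$embed_dim; C <- cfg$in_channels; P <- cfg$patch_size
  mid <- cfg$stem_mid_channels
  stem <- (9 * C * mid + mid) + 2 * mid + (9 * mid * C + C) + 2 * C +
    (C * C + C) + 2 * C
  sa <- 9 * 2 * C + C
  backbone <- (P^2 * C * D + D) + D + cfg$n_tokens * D +
    cfg$depth * ledger_layer_params(D, cfg$mlp_ratio) + 2 * D
  heads <- (D * cfg$n_binary + cfg$n_binary) +
    (D * cfg$n_ternary + cfg$n_ternary)
  total <- backbone + heads
  if (variant %in% c("full", "no_spatial_attention")) total <- total + stem
  if (variant %in% c("full", "no_residual")) total <- total + sa
  total
}
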