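# Vision-transformer backbone: patch embedding, CLS token + learnable position
# embeddings, and pre-norm residual encoder layers
#   f' = MHSA(LN(f)) + f ;  f = FFN(LN(f')) + f'
# with multi-head self-attention and a GELU MLP of width mlp_ratio * embed_dim.

## ---- reshape conventions ---------------------------------------------------

# Row-major, channel-last flattening of an h x w x c block: element (i, j, c)
# sits at position ((i-1)*w + (j-1))*C + c. Used both for patch flattening and
# the CLS <-> spatial-map reshape, and is an exact bijection.
map_to_vec <- function(m) {
  as.vector(aperm(m, c(3, 2, 1)))
}

vec_to_map <- function(v, h, w, c) {
  aperm(array(v, c(c, w, h)), c(3, 2, 1))
}

## ---- patch embedding -------------------------------------------------------

# Slice an H x W x C feature map into non-overlapping P x P patches in
# row-major grid order and flatten each (row-major, channel-last).
# Returns an n_patches x (P*P*C) matrix.
patchify <- function(feature, patch_size) {
  d <- dim(feature)
  P <- patch_size
  if (d[1] %% P != 0 || d[2] %% P != 0) {
    stop(sprintf("feature map %dx%d not divisible by patch size %d (no implicit padding)",
                 d[1], d[2], P))
  }
  gh <- d[1] %/% P
  gw <- d[2] %/% P
  out <- matrix(0, gh * gw, P * P * d[3])
  k <- 0L
  for (gi in seq_len(gh)) {
    for (gj in seq_len(gw)) {
      k <- k + 1L
      blk <- feature[(gi - 1L) * P + seq_len(P),
                     (gj - 1L) * P + seq_len(P), , drop = FALSE]
      out[k, ] <- map_to_vec(blk)
    }
  }
  out
}

# Scatter patch-vector gradients back to a feature-map gradient.
unpatchify_grad <- function(dpatches, dims, patch_size) {
  P <- patch_size
  gh <- dims[1] %/% P
  gw <- dims[2] %/% P
  g <- array(0, dims)
  k <- 0L
  for (gi in seq_len(gh)) {
    for (gj in seq_len(gw)) {
      k <- k + 1L
      g[(gi - 1L) * P + seq_len(P),
        (gj - 1L) * P + seq_len(P), ] <- vec_to_map(dpatches[k, ], P, P, dims[3])
    }
  }
  g
}

#' Patch embedding
#'
#' Divides a feature map into fixed-size non-overlapping square patches
#' (row-major over the patch grid), flattens each patch row-major with the
#' channel index fastest, and applies the model's trainable linear projection
#' to `embed_dim`. The CLS token is not included; see
#' [add_cls_and_positions()].
#'
#' @param feature An `H x W x C` array with `H`, `W` divisible by the patch
#'   size.
#' @param model A `flater_model`.
#' @return An `n_patches x embed_dim` matrix of tokens.
#' @export
patch_embed <- function(feature, model) {
  stopifnot(inherits(model, "flater_model"))
  patches <- patchify(feature, model$config$patch_size)
  linear_fwd(patches, model$params$patch$W, model$params$patch$b)$out
}

#' Prepend the CLS token and add position embeddings
#'
#' Prepends the learnable CLS embedding to a patch-token sequence and adds the
#' learnable position-embedding table elementwise (one row per position,
#' including the CLS position).
#'
#' @param tokens An `n_patches x embed_dim` matrix (without CLS).
#' @param model A `flater_model`.
#' @return An `(n_patches + 1) x embed_dim` matrix; row 1 is the CLS token.
#' @export
add_cls_and_positions <- function(tokens, model) {
  stopifnot(inherits(model, "flater_model"))
  p <- model$params
  L <- nrow(tokens) + 1L
  if (nrow(p$pos) != L) {
    stop(sprintf(
      "position-embedding table has %d rows but the sequence needs %d; no silent interpolation",
      nrow(p$pos), L))
  }
  rbind(p$cls, tokens) + p$pos
}

## ---- multi-head self-attention ---------------------------------------------

# x: L x D. p: list(Wq, Wk, Wv, bq, bk, bv, Wo, bo). num_heads heads of width
# D / num_heads; scaled dot-product attention per head.
mhsa_fwd <- function(x, p, num_heads) {
  L <- nrow(x); D <- ncol(x)
  dh <- D %/% num_heads
  Q <- sweep(x %*% p$Wq, 2L, p$bq, "+")
  K <- sweep(x %*% p$Wk, 2L, p$bk, "+")
  V <- sweep(x %*% p$Wv, 2L, p$bv, "+")
  O <- matrix(0, L, D)
  A <- vector("list", num_heads)
  for (h in seq_len(num_heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
    A[[h]] <- row_softmax(S)
    O[, cols] <- A[[h]] %*% V[, cols, drop = FALSE]
  }
  lin <- linear_fwd(O, p$Wo, p$bo)
  list(out = lin$out, x = x, Q = Q, K = K, V = V, A = A, O = O, dh = dh)
}

mhsa_bwd <- function(dy, cache, p, num_heads) {
  dh <- cache$dh
  dO <- dy %*% t(p$Wo)
  dWo <- crossprod(cache$O, dy)
  dbo <- colSums(dy)
  dQ <- matrix(0, nrow(dO), ncol(dO))
  dK <- dQ; dV <- dQ
  for (h in seq_len(num_heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    A <- cache$A[[h]]
    Vh <- cache$V[, cols, drop = FALSE]
    dOh <- dO[, cols, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dV[, cols] <- crossprod(A, dOh)
    dS <- row_softmax_bwd(dA, A) / sqrt(dh)
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE]
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE])
  }
  x <- cache$x
  list(dx = dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv),
       grads = list(Wq = crossprod(x, dQ), bq = colSums(dQ),
                    Wk = crossprod(x, dK), bk = colSums(dK),
                    Wv = crossprod(x, dV), bv = colSums(dV),
                    Wo = dWo, bo = dbo))
}

## ---- encoder layer ---------------------------------------------------------

encoder_layer_init <- function(config) {
  D <- config$embed_dim
  Hd <- as.integer(round(config$mlp_ratio * D))
  list(
    ln1_gamma = rep(1, D), ln1_beta = numeric(D),
    attn = list(Wq = tn_matrix(D, D), bq = numeric(D),
                Wk = tn_matrix(D, D), bk = numeric(D),
                Wv = tn_matrix(D, D), bv = numeric(D),
                Wo = tn_matrix(D, D), bo = numeric(D)),
    ln2_gamma = rep(1, D), ln2_beta = numeric(D),
    mlp = list(W1 = tn_matrix(D, Hd), b1 = numeric(Hd),
               W2 = tn_matrix(Hd, D), b2 = numeric(D))
  )
}

encoder_layer_fwd <- function(x, p, config, training = FALSE) {
  ln1 <- layernorm_fwd(x, p$ln1_gamma, p$ln1_beta)
  att <- mhsa_fwd(ln1$out, p$attn, config$num_heads)
  dr1 <- dropout_fwd(att$out, config$dropout, training)
  x2 <- x + dr1$out
  ln2 <- layernorm_fwd(x2, p$ln2_gamma, p$ln2_beta)
  h1 <- linear_fwd(ln2$out, p$mlp$W1, p$mlp$b1)
  act <- gelu(h1$out)
  h2 <- linear_fwd(act, p$mlp$W2, p$mlp$b2)
  dr2 <- dropout_fwd(h2$out, config$dropout, training)
  list(out = x2 + dr2$out,
       cache = list(ln1 = ln1, att = att, dr1 = dr1, x2 = x2, ln2 = ln2,
                    h1 = h1, act = act, h2 = h2, dr2 = dr2))
}

encoder_layer_bwd <- function(dy, cache, p, config) {
  g <- list()
  d2 <- dropout_bwd(dy, cache$dr2)
  l2 <- linear_bwd(d2, cache$h2, p$mlp$W2)
  g$mlp <- list(W2 = l2$dW, b2 = l2$db)
  dact <- l2$dx * gelu_grad(cache$h1$out)
  l1 <- linear_bwd(dact, cache$h1, p$mlp$W1)
  g$mlp$W1 <- l1$dW; g$mlp$b1 <- l1$db
  lnb2 <- layernorm_bwd(l1$dx, cache$ln2, p$ln2_gamma)
  g$ln2_gamma <- lnb2$dgamma; g$ln2_beta <- lnb2$dbeta
  dx2 <- dy + lnb2$dx

  d1 <- dropout_bwd(dx2, cache$dr1)
  attb <- mhsa_bwd(d1, cache$att, p$attn, config$num_heads)
  g$attn <- attb$grads
  lnb1 <- layernorm_bwd(attb$dx, cache$ln1, p$ln1_gamma)
  g$ln1_gamma <- lnb1$dgamma; g$ln1_beta <- lnb1$dbeta
  list(dx = dx2 + lnb1$dx, grads = g)
}

#' Transformer encoder layer forward pass
#'
#' One pre-norm residual encoder layer: multi-head self-attention over the
#' layer-normalised input added back to the input, followed by a GELU MLP over
#' the layer-normalised intermediate added back again. Shape is preserved.
#'
#' @param tokens An `L x embed_dim` token matrix.
#' @param model A `flater_model`.
#' @param layer Which encoder layer's parameters to use (default 1).
#' @return An `L x embed_dim` matrix.
#' @export
encoder_layer <- function(tokens, model, layer = 1L) {
  stopifnot(inherits(model, "flater_model"))
  if (ncol(tokens) != model$config$embed_dim) {
    stop(sprintf("tokens have dim %d, model expects %d",
                 ncol(tokens), model$config$embed_dim))
  }
  encoder_layer_fwd(tokens, model$params$layers[[layer]], model$config)$out
}
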