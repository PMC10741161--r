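# CLS-token spatial attention. The final CLS embedding (length embed_dim =
# a^2 * C) is reshaped row-major/channel-last to an a x a x C map, max- and
# average-pooled along the channel axis, the two a x a maps concatenated and
# passed through a padded 3x3 convolution (2 -> C channels) and a sigmoid.
# "literal" returns the sigmoid map, reshaped back to a vector, as the
# classification feature; "modulated" multiplies the sigmoid map elementwise
# into the reshaped CLS map first.

spatial_attn_init <- function(config) {
  C <- config$in_channels
  list(conv_w = tn_array(c(3, 3, 2, C)),
       conv_b = numeric(C))
}

spatial_attn_fwd <- function(cls_vec, p, config) {
  a <- config$attn_grid
  C <- config$in_channels
  F2p <- vec_to_map(cls_vec, a, a, C)
  mx <- F2p[, , 1]
  for (c in seq_len(C)[-1]) mx <- pmax(mx, F2p[, , c])
  amax <- apply(F2p, c(1, 2), which.max)   # routing for the max-pool backward
  av <- apply(F2p, c(1, 2), mean)
  pooled <- array(c(mx, av), c(a, a, 2))
  cv <- conv2d_fwd(pooled, p$conv_w, p$conv_b, stride = 1L, pad = 1L)
  s <- sigmoid(cv$out)
  out_map <- if (config$attention_variant == "modulated") s * F2p else s
  list(out = map_to_vec(out_map),
       cache = list(F2p = F2p, amax = amax, cv = cv, s = s))
}

spatial_attn_bwd <- function(dout, cache, p, config) {
  a <- config$attn_grid
  C <- config$in_channels
  dmap <- vec_to_map(dout, a, a, C)
  s <- cache$s
  if (config$attention_variant == "modulated") {
    ds <- dmap * cache$F2p
    dF2p_direct <- dmap * s
  } else {
    ds <- dmap
    dF2p_direct <- array(0, c(a, a, C))
  }
  dconv_out <- ds * s * (1 - s)
  cb <- conv2d_bwd(dconv_out, cache$cv, p$conv_w)
  # split pooled gradient back: channel 1 max (route to argmax), channel 2 avg
  dF2p <- dF2p_direct
  dmx <- cb$dx[, , 1]
  dav <- cb$dx[, , 2] / C
  for (c in seq_len(C)) {
    dF2p[, , c] <- dF2p[, , c] + dav + dmx * (cache$amax == c)
  }
  list(dcls = map_to_vec(dF2p),
       grads = list(conv_w = cb$dW, conv_b = cb$db))
}

#' Spatial attention over the CLS embedding
#'
#' Reshapes the CLS vector to a small spatial map, pools across channels
#' (max and average), convolves the concatenated pools with a 3x3 kernel and
#' applies a sigmoid. With `attention_variant = "literal"` the sigmoid map is
#' itself the returned feature (values strictly in (0, 1)); with
#' `"modulated"` it re-weights the reshaped CLS map elementwise.
#'
#' @param cls_vec Numeric vector of length `embed_dim`.
#' @param model A `flater_model`.
#' @return Numeric vector of length `embed_dim`.
#' @export
spatial_attention <- function(cls_vec, model) {
  stopifnot(inherits(model, "flater_model"))
  if (is.null(model$params$sa)) {
    stop(sprintf("model variant '%s' has no spatial-attention block",
                 model$variant))
  }
  if (length(cls_vec) != model$config$embed_dim) {
    stop(sprintf("cls_vec has length %d, expected embed_dim %d",
                 length(cls_vec), model$config$embed_dim))
  }
  spatial_attn_fwd(cls_vec, model$params$sa, model$config)$out
}
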