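# Model assembly: residual stem -> patch embedding -> CLS + position
# embeddings -> N encoder layers -> final layer norm -> CLS row -> spatial
# attention -> two linear heads (binary, ternary) sharing all upstream
# parameters. Ablation variants drop the stem and/or the spatial-attention
# block.

FLATER_VARIANTS <- c("full", "no_residual", "no_spatial_attention", "vit_only")

#' Build a model
#'
#' Initialises all trainable parameters (truncated normal, sd 0.02, for
#' embeddings, linear and convolution weights; ones for normalisation gains;
#' zeros for biases and shifts) under the given seed, together with the
#' batch-norm running-statistic buffers.
#'
#' @param config A [flater_config()].
#' @param variant One of `"full"` (default), `"no_residual"` (patches taken
#'   directly from the preprocessed image), `"no_spatial_attention"` (heads
#'   consume the final CLS embedding directly) or `"vit_only"` (both removed).
#' @param seed Integer seed controlling initialisation.
#' @return A `flater_model` object.
#' @examples
#' m <- flater_model(flater_config(image_size = 32, patch_size = 16,
#'                                 embed_dim = 12, depth = 1, num_heads = 2),
#'                   seed = 1)
#' count_trainable_parameters(m)
#' @export
flater_model <- function(config, variant = "full", seed = 1L) {
  stopifnot(inherits(config, "flater_config"))
  if (!variant %in% FLATER_VARIANTS) {
    stop(sprintf("unknown variant '%s'; valid variants: %s",
                 variant, paste(FLATER_VARIANTS, collapse = ", ")))
  }
  set.seed(seed)
  D <- config$embed_dim
  P <- config$patch_size
  C <- config$in_channels
  params <- list()
  if (variant %in% c("full", "no_spatial_attention")) {
    params$stem <- stem_init(config)
  }
  params$patch <- list(W = tn_matrix(P * P * C, D), b = numeric(D))
  params$cls <- trunc_normal(D)
  params$pos <- tn_matrix(config$n_tokens, D)
  params$layers <- lapply(seq_len(config$depth),
                          function(i) encoder_layer_init(config))
  params$ln_f_gamma <- rep(1, D)
  params$ln_f_beta <- numeric(D)
  if (variant %in% c("full", "no_residual")) {
    params$sa <- spatial_attn_init(config)
  }
  params$head_bin <- list(W = tn_matrix(D, config$n_binary),
                          b = numeric(config$n_binary))
  params$head_ter <- list(W = tn_matrix(D, config$n_ternary),
                          b = numeric(config$n_ternary))

  buffers <- if (!is.null(params$stem)) stem_buffers_init(config) else list()
  structure(list(config = config, variant = variant, params = params,
                 buffers = buffers, seed = as.integer(seed)),
            class = "flater_model")
}

#' @export
print.flater_model <- function(x, ...) {
  cat(sprintf("<flater_model> variant '%s', %s trainable parameters\n",
              x$variant, format(count_trainable_parameters(x), big.mark = ",")))
  print(x$config)
  invisible(x)
}

#' Construct an ablation variant
#'
#' Builds a model with the residual stem and/or the spatial-attention block
#' removed, matching the four rows of the ablation study: the full model,
#' without the residual block, without spatial attention, and the bare ViT
#' backbone.
#'
#' @param config A [flater_config()].
#' @param variant `"full"`, `"no_residual"`, `"no_spatial_attention"` or
#'   `"vit_only"`.
#' @param seed Initialisation seed.
#' @return A `flater_model`.
#' @export
make_ablation_variant <- function(config, variant, seed = 1L) {
  flater_model(config, variant = variant, seed = seed)
}

#' Count trainable parameters
#'
#' Exact count of independently trainable scalars (batch-norm running
#' statistics are buffers and excluded).
#'
#' @param model A `flater_model`.
#' @return Integer-valued count.
#' @export
count_trainable_parameters <- function(model) {
  stopifnot(inherits(model, "flater_model"))
  sum(vapply(rapply(model$params, length, how = "unlist"), identity,
             numeric(1)))
}

## ---- forward / backward ----------------------------------------------------

# Internal batch layout: H x W x B x C (spatial fastest, then batch, then
# channel) -- the layout the batched stem operates on natively.
as_batch <- function(images) {
  if (is.list(images)) {
    d <- dim(images[[1]])
    xb <- array(0, c(d[1], d[2], length(images), d[3]))
    for (b in seq_along(images)) xb[, , b, ] <- images[[b]]
    xb
  } else if (length(dim(images)) == 3) {
    d <- dim(images)
    aperm(array(images, c(d, 1L)), c(1, 2, 4, 3))
  } else {
    images
  }
}

#' Model forward pass
#'
#' Runs a batch of preprocessed images through the full network and returns
#' the raw logits of both classification heads.
#'
#' @param model A `flater_model`.
#' @param images A single `H x W x 3` array, an `H x W x 3 x B` array, or a
#'   list of `H x W x 3` arrays; `H = W =` the configured `image_size`.
#' @param training Logical; batch-norm/dropout mode.
#' @return A list with `binary_logits` (`B x 2`) and `ternary_logits`
#'   (`B x 3`; columns ordered ulcerative colitis, polyps, esophagitis).
#' @export
model_forward <- function(model, images, training = FALSE) {
  model_forward_full(model, images, training = training)$out
}

# Full forward keeping caches (training) and updated buffers.
model_forward_full <- function(model, images, training = FALSE) {
  cfg <- model$config
  p <- model$params
  xb <- as_batch(images)
  d <- dim(xb)
  if (d[1] != cfg$image_size || d[2] != cfg$image_size ||
      d[4] != cfg$in_channels) {
    stop(sprintf("input resolution %dx%dx%d does not match the expected %dx%dx%d",
                 d[1], d[2], d[4],
                 cfg$image_size, cfg$image_size, cfg$in_channels))
  }
  B <- d[3]
  buffers <- model$buffers

  if (!is.null(p$stem)) {
    st <- stem_batch_fwd(xb, p$stem, buffers, cfg, training = training)
    feat <- st$out
    buffers <- st$buffers
  } else {
    st <- NULL
    feat <- xb
  }

  per <- vector("list", B)
  bin_logits <- matrix(0, B, cfg$n_binary)
  ter_logits <- matrix(0, B, cfg$n_ternary)
  for (b in seq_len(B)) {
    patches <- patchify(feat[, , b, , drop = TRUE], cfg$patch_size)
    emb <- linear_fwd(patches, p$patch$W, p$patch$b)
    x <- rbind(p$cls, emb$out) + p$pos
    layers <- vector("list", cfg$depth)
    for (l in seq_len(cfg$depth)) {
      lf <- encoder_layer_fwd(x, p$layers[[l]], cfg, training = training)
      layers[[l]] <- lf$cache
      x <- lf$out
    }
    lnf <- layernorm_fwd(x, p$ln_f_gamma, p$ln_f_beta)
    f2 <- lnf$out[1, ]
    if (!is.null(p$sa)) {
      sa <- spatial_attn_fwd(f2, p$sa, cfg)
      f <- sa$out
    } else {
      sa <- NULL
      f <- f2
    }
    bin_logits[b, ] <- drop(f %*% p$head_bin$W) + p$head_bin$b
    ter_logits[b, ] <- drop(f %*% p$head_ter$W) + p$head_ter$b
    per[[b]] <- list(emb = emb, layers = layers, lnf = lnf, sa = sa, f = f)
  }

  list(out = list(binary_logits = bin_logits, ternary_logits = ter_logits),
       cache = list(stem = st, per = per, dims = d),
       buffers = buffers)
}

# Backward from head-logit gradients; returns grads mirroring model$params.
model_backward <- function(model, cache, dbin, dter) {
  cfg <- model$config
  p <- model$params
  d <- cache$dims
  B <- d[3]
  g <- zero_like(p)

  dfeat <- if (!is.null(p$stem)) array(0, d) else NULL
  for (b in seq_len(B)) {
    pc <- cache$per[[b]]
    f <- pc$f
    db <- dbin[b, ]
    dt <- dter[b, ]
    g$head_bin$W <- g$head_bin$W + outer(f, db)
    g$head_bin$b <- g$head_bin$b + db
    g$head_ter$W <- g$head_ter$W + outer(f, dt)
    g$head_ter$b <- g$head_ter$b + dt
    df <- drop(p$head_bin$W %*% db) + drop(p$head_ter$W %*% dt)
    if (!is.null(p$sa)) {
      sab <- spatial_attn_bwd(df, pc$sa$cache, p$sa, cfg)
      g$sa$conv_w <- g$sa$conv_w + sab$grads$conv_w
      g$sa$conv_b <- g$sa$conv_b + sab$grads$conv_b
      df2 <- sab$dcls
    } else {
      df2 <- df
    }
    dx <- matrix(0, cfg$n_tokens, cfg$embed_dim)
    dlnf_out <- dx
    dlnf_out[1, ] <- df2
    lnb <- layernorm_bwd(dlnf_out, pc$lnf, p$ln_f_gamma)
    g$ln_f_gamma <- g$ln_f_gamma + lnb$dgamma
    g$ln_f_beta <- g$ln_f_beta + lnb$dbeta
    dx <- lnb$dx
    for (l in rev(seq_len(cfg$depth))) {
      lb <- encoder_layer_bwd(dx, pc$layers[[l]], p$layers[[l]], cfg)
      g$layers[[l]] <- add_grads(g$layers[[l]], lb$grads)
      dx <- lb$dx
    }
    g$cls <- g$cls + dx[1, ]
    g$pos <- g$pos + dx
    demb <- dx[-1, , drop = FALSE]
    lb <- linear_bwd(demb, pc$emb, p$patch$W)
    g$patch$W <- g$patch$W + lb$dW
    g$patch$b <- g$patch$b + lb$db
    if (!is.null(p$stem)) {
      dfeat[, , b, ] <- unpatchify_grad(
        lb$dx, c(cfg$image_size, cfg$image_size, cfg$in_channels),
        cfg$patch_size)
    }
  }
  if (!is.null(p$stem)) {
    sb <- stem_batch_bwd(dfeat, cache$stem$cache, p$stem)
    g$stem <- sb$grads
  }
  g
}

# Recursive zero-initialised copy of a parameter tree.
zero_like <- function(x) {
  if (is.list(x)) {
    lapply(x, zero_like)
  } else {
    y <- x
    y[] <- 0
    y
  }
}

add_grads <- function(a, b) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- add_grads(a[[nm]], b[[nm]])
    a
  } else {
    a + b
  }
}

## ---- checkpoints ------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' `save_checkpoint()` serialises parameters, batch-norm buffers, config,
#' variant, seed and optional training history/config to `path`, and writes a
#' plain-JSON sidecar (`<path>.json`) with the config, seed, a parameter-name
#' manifest with shapes, and a config hash. `load_checkpoint()` restores the
#' model (bitwise) and refuses to proceed when the stored config hash does not
#' match the re-computed one.
#'
#' @param model A `flater_model`.
#' @param path File path for the checkpoint.
#' @param history Optional training history (data frame).
#' @param train_config Optional list of training hyperparameters.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns a list with `model`, `history` and `train_config`.
#' @export
save_checkpoint <- function(model, path, history = NULL, train_config = NULL) {
  stopifnot(inherits(model, "flater_model"))
  hash <- config_hash(model$config)
  obj <- list(params = model$params, buffers = model$buffers,
              config = unclass(model$config), variant = model$variant,
              seed = model$seed, history = history,
              train_config = train_config, config_hash = hash)
  saveRDS(obj, path)
  manifest <- param_manifest(model$params)
  sidecar <- list(config = unclass(model$config), variant = model$variant,
                  seed = model$seed, config_hash = hash,
                  n_trainable = count_trainable_parameters(model),
                  parameters = manifest)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- obj$config
  class(cfg) <- "flater_config"
  if (!identical(unname(config_hash(cfg)), unname(obj$config_hash))) {
    stop("checkpoint config hash mismatch: file is inconsistent or corrupted")
  }
  model <- structure(list(config = cfg, variant = obj$variant,
                          params = obj$params, buffers = obj$buffers,
                          seed = obj$seed),
                     class = "flater_model")
  list(model = model, history = obj$history, train_config = obj$train_config)
}

# Flat name -> dimension manifest of a parameter tree.
param_manifest <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    full <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    x <- p[[nm]]
    if (is.list(x)) {
      out <- c(out, param_manifest(x, full))
    } else {
      out[[full]] <- if (is.null(dim(x))) length(x) else dim(x)
    }
  }
  out
}

## ---- backbone weight loading -------------------------------------------------

#' Load backbone weights from a checkpoint archive
#'
#' Overwrites the transformer backbone (patch projection, CLS embedding,
#' position embeddings, encoder layers, final layer norm) of `model` with the
#' values stored in a checkpoint archive written by [save_checkpoint()]
#' (e.g. from an externally pre-trained backbone). The stem, the
#' spatial-attention block and the classification heads keep their fresh
#' initialisation. When the archive has more encoder layers than the model,
#' the leading layers are used only if `truncate = TRUE`; fewer layers, or any
#' shape mismatch, is an error reporting every offending parameter.
#'
#' @param model A `flater_model`.
#' @param archive Path to a checkpoint written by [save_checkpoint()].
#' @param truncate Allow loading the first `depth` layers of a deeper archive.
#' @return A list: `model` (updated) and `report` (data frame with columns
#'   `parameter` and `status`, one of `"loaded"`/`"skipped"`).
#' @export
load_backbone_weights <- function(model, archive, truncate = FALSE) {
  stopifnot(inherits(model, "flater_model"))
  src <- readRDS(archive)
  sp <- src$params
  D_src <- ncol(sp$patch$W)
  D <- model$config$embed_dim
  if (D_src != D) {
    stop(sprintf("embed_dim mismatch: archive has %d, model expects %d",
                 D_src, D))
  }
  depth_src <- length(sp$layers)
  depth <- model$config$depth
  if (depth_src < depth) {
    stop(sprintf("archive has %d encoder layers but the model needs %d",
                 depth_src, depth))
  }
  if (depth_src > depth && !truncate) {
    stop(sprintf(
      "archive has %d encoder layers, model has %d; pass truncate = TRUE to load the first %d",
      depth_src, depth, depth))
  }

  backbone <- c("patch", "cls", "pos", "layers", "ln_f_gamma", "ln_f_beta")
  mismatches <- character(0)
  man_model <- param_manifest(model$params[backbone])
  sp_bb <- sp[backbone]
  sp_bb$layers <- sp_bb$layers[seq_len(depth)]
  man_src <- param_manifest(sp_bb)
  for (nm in names(man_model)) {
    if (!identical(man_model[[nm]], man_src[[nm]])) {
      mismatches <- c(mismatches, sprintf(
        "%s: archive [%s] vs model [%s]", nm,
        paste(man_src[[nm]], collapse = "x"),
        paste(man_model[[nm]], collapse = "x")))
    }
  }
  if (length(mismatches)) {
    stop(paste(c("backbone shape mismatch; nothing loaded:", mismatches),
               collapse = "\n  "))
  }
  for (nm in backbone) model$params[[nm]] <- sp_bb[[nm]]

  man_all <- param_manifest(model$params)
  status <- ifelse(grepl("^(patch|cls|pos|layers|ln_f_gamma|ln_f_beta)",
                         names(man_all)), "loaded", "skipped")
  list(model = model,
       report = data.frame(parameter = names(man_all), status = status,
                           stringsAsFactors = FALSE))
}
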