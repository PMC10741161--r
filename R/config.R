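#' Model configuration
#'
#' Collects every architectural hyperparameter of the network: input geometry,
#' residual-stem widths, transformer depth/width, spatial-attention variant and
#' head sizes. The defaults describe the full-size model: 224x224 RGB input,
#' 16x16 patches, embedding dimension 768 = 16 x 16 x 3 (so a patch token has
#' exactly one scalar per input pixel value), 12 encoder layers with 12
#' attention heads, and an MLP expansion ratio of 4 -- the ViT-B/16 geometry
#' behind the backbone.
#'
#' `embed_dim` must be expressible as `a^2 * in_channels` for an integer `a`:
#' the spatial-attention block reshapes the final CLS embedding to an
#' `a x a x in_channels` feature map. For the defaults `a = 16`, equal to the
#' patch size, so `embed_dim = patch_size^2 * in_channels` holds exactly.
#' Smaller desk-scale configurations (e.g. `embed_dim = 48`, so `a = 4`) are
#' allowed; the patch projection is a general linear map and absorbs the
#' dimension change.
#'
#' @param image_size Input resolution in pixels (square), divisible by
#'   `patch_size` and by `stem_stride`.
#' @param patch_size Side length of the square non-overlapping patches.
#' @param in_channels Number of image channels (3 for RGB).
#' @param stem_mid_channels Width of the residual stem's hidden stage.
#' @param stem_stride Stride of the stem's first convolution (>= 2); the
#'   matching bilinear upsample restores the input resolution.
#' @param embed_dim Token embedding dimension; must equal `a^2 * in_channels`
#'   for integer `a` and be divisible by `num_heads`.
#' @param depth Number of transformer encoder layers (12, 6 and 4 are the
#'   studied depths; any positive integer is accepted).
#' @param num_heads Number of self-attention heads.
#' @param mlp_ratio Hidden-width multiplier of each encoder layer's MLP.
#' @param attention_variant `"modulated"` (default) multiplies the sigmoid
#'   attention map elementwise into the reshaped CLS feature, re-weighting
#'   its regions; `"literal"` returns the sigmoid map itself as the
#'   classification feature. See the methods vignette for the trade-off.
#' @param n_binary,n_ternary Output sizes of the two classification heads.
#' @param dropout Dropout probability applied inside encoder layers during
#'   training (0 disables).
#'
#' @return An object of class `flater_config` (a validated list). The derived
#'   fields `n_patches`, `n_tokens` (patches + CLS) and `attn_grid` (`a`
#'   above) are included.
#' @examples
#' cfg <- flater_config()
#' cfg$n_tokens   # 197 = 224^2/16^2 + 1
#' @export
flater_config <- function(image_size = 224,
                          patch_size = 16,
                          in_channels = 3,
                          stem_mid_channels = 64,
                          stem_stride = 2,
                          embed_dim = NULL,
                          depth = 12,
                          num_heads = 12,
                          mlp_ratio = 4,
                          attention_variant = c("modulated", "literal"),
                          n_binary = 2,
                          n_ternary = 3,
                          dropout = 0) {
  attention_variant <- match.arg(attention_variant)
  if (is.null(embed_dim)) embed_dim <- patch_size^2 * in_channels

  stopifnot(
    image_size >= 1, patch_size >= 1, in_channels >= 1,
    stem_mid_channels >= 1, depth >= 1, num_heads >= 1, mlp_ratio > 0,
    n_binary >= 2, n_ternary >= 2, dropout >= 0, dropout < 1
  )
  if (stem_stride < 2) {
    stop("stem_stride must be >= 2 (the stem downsamples before upsampling)")
  }
  if (image_size %% patch_size != 0) {
    stop(sprintf("image_size (%d) must be divisible by patch_size (%d)",
                 image_size, patch_size))
  }
  if (image_size %% stem_stride != 0) {
    stop(sprintf("image_size (%d) must be divisible by stem_stride (%d)",
                 image_size, stem_stride))
  }
  if (embed_dim %% num_heads != 0) {
    stop(sprintf("embed_dim (%d) must be divisible by num_heads (%d)",
                 embed_dim, num_heads))
  }
  a <- sqrt(embed_dim / in_channels)
  if (abs(a - round(a)) > 1e-9) {
    stop(sprintf(
      paste0("embed_dim (%d) must equal a^2 x in_channels (%d) for an ",
             "integer a: the spatial-attention block reshapes the CLS ",
             "embedding to an a x a x %d map"),
      embed_dim, in_channels, in_channels))
  }

  n_patches <- (image_size / patch_size)^2
  cfg <- list(
    image_size = as.integer(image_size),
    patch_size = as.integer(patch_size),
    in_channels = as.integer(in_channels),
    stem_mid_channels = as.integer(stem_mid_channels),
    stem_stride = as.integer(stem_stride),
    embed_dim = as.integer(embed_dim),
    depth = as.integer(depth),
    num_heads = as.integer(num_heads),
    mlp_ratio = mlp_ratio,
    attention_variant = attention_variant,
    n_binary = as.integer(n_binary),
    n_ternary = as.integer(n_ternary),
    dropout = dropout,
    n_patches = as.integer(n_patches),
    n_tokens = as.integer(n_patches + 1),
    attn_grid = as.integer(round(a))
  )
  class(cfg) <- "flater_config"
  cfg
}

#' @export
print.flater_config <- function(x, ...) {
  cat(sprintf(
    paste0("<flater_config> %dx%dx%d input, patch %d (%d tokens incl. CLS), ",
           "embed_dim %d, depth %d, heads %d, mlp_ratio %g,\n",
           "  stem %d->%d->%d stride %d, spatial attention: %s grid %dx%d, ",
           "heads %d-way + %d-way, dropout %g\n"),
    x$image_size, x$image_size, x$in_channels, x$patch_size, x$n_tokens,
    x$embed_dim, x$depth, x$num_heads, x$mlp_ratio,
    x$in_channels, x$stem_mid_channels, x$in_channels, x$stem_stride,
    x$attention_variant, x$attn_grid, x$attn_grid, x$n_binary, x$n_ternary,
    x$dropout))
  invisible(x)
}

#' Canonical class vocabulary
#'
#' The four image classes: `"normal"` plus the three disease categories in
#' ternary-head order (class 0 = ulcerative colitis, 1 = polyps,
#' 2 = esophagitis).
#' @return Character vectors of class names.
#' @export
flater_classes <- function() {
  c("normal", disease_classes())
}

#' @rdname flater_classes
#' @export
disease_classes <- function() {
  c("ulcerative-colitis", "polyps", "esophagitis")
}

#' @rdname flater_classes
#' @export
binary_classes <- function() {
  c("normal", "diseased")
}

# Internal: md5 of a config's canonical JSON, used to guard checkpoint loads.
config_hash <- function(config) {
  stopifnot(inherits(config, "flater_config"))
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(js, f)
  unname(tools::md5sum(f))
}
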