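# Image preprocessing. Training: bilinear resize (short side to
# 8/7 x target), random resized crop to the target resolution, random
# horizontal flip (p = 0.5), scale to [0, 1], per-channel normalisation with
# mean (0.485, 0.456, 0.406) and std (0.229, 0.224, 0.225). Evaluation:
# deterministic short-side resize, centre crop, same normalisation. The
# normalisation constants are applied identically across splits.

IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_STD <- c(0.229, 0.224, 0.225)

normalize_channels <- function(x, mean = IMAGENET_MEAN, std = IMAGENET_STD) {
  for (c in seq_len(dim(x)[3])) {
    x[, , c] <- (x[, , c] - mean[c]) / std[c]
  }
  x
}

check_rgb <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3 || d[3] != 3) {
    stop("expected an H x W x 3 RGB image")
  }
  d
}

resize_short_side <- function(image, short) {
  d <- dim(image)
  if (d[1] <= d[2]) {
    resize_bilinear(image, short, as.integer(round(short * d[2] / d[1])))
  } else {
    resize_bilinear(image, as.integer(round(short * d[1] / d[2])), short)
  }
}

#' Training transform
#'
#' Augmenting preprocessing for training images: bilinear resize of the short
#' side to `ceiling(out_size * 8 / 7)` (256 for the default 224), a random
#' resized crop whose area covers `scale_range` of the resized image with
#' aspect ratio drawn from `aspect_range`, a horizontal flip with probability
#' 0.5, scaling to `[0, 1]`, and per-channel normalisation with mean
#' (0.485, 0.456, 0.406) and std (0.229, 0.224, 0.225). Consumes the R RNG
#' stream; seed the session for reproducible augmentation.
#'
#' The crop-scale floor of 0.7 is deliberately conservative: lesions can
#' occupy a small fraction of the frame and aggressive crops could excise
#' them.
#'
#' @param image `H x W x 3` array with values in 0..255 (or a record from the
#'   generator).
#' @param out_size Output resolution (square), default 224.
#' @param scale_range,aspect_range Random-resized-crop parameter ranges.
#' @return A normalised `out_size x out_size x 3` array.
#' @export
train_transform <- function(image, out_size = 224L,
                            scale_range = c(0.7, 1.0),
                            aspect_range = c(3 / 4, 4 / 3)) {
  if (is.list(image)) image <- image$image
  check_rgb(image)
  short <- as.integer(ceiling(out_size * 8 / 7))
  img <- resize_short_side(image, short)
  d <- dim(img)

  # random resized crop: sample target area and aspect, fall back to a centre
  # crop when the sampled box does not fit
  for (attempt in 1:10) {
    area <- stats::runif(1, scale_range[1], scale_range[2]) * d[1] * d[2]
    logr <- stats::runif(1, log(aspect_range[1]), log(aspect_range[2]))
    ar <- exp(logr)
    cw <- as.integer(round(sqrt(area * ar)))
    ch <- as.integer(round(sqrt(area / ar)))
    if (cw <= d[2] && ch <= d[1]) {
      top <- sample.int(d[1] - ch + 1L, 1)
      left <- sample.int(d[2] - cw + 1L, 1)
      img <- img[top:(top + ch - 1L), left:(left + cw - 1L), , drop = FALSE]
      break
    }
    if (attempt == 10) {
      side <- min(d[1], d[2])
      top <- (d[1] - side) %/% 2 + 1L
      left <- (d[2] - side) %/% 2 + 1L
      img <- img[top:(top + side - 1L), left:(left + side - 1L), ,
                 drop = FALSE]
    }
  }
  img <- resize_bilinear(img, out_size, out_size)
  if (stats::runif(1) < 0.5) {
    img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  }
  normalize_channels(img / 255)
}

#' Evaluation transform
#'
#' Deterministic preprocessing: bilinear resize of the short side to
#' `ceiling(out_size * 8 / 7)` (256 for 224), centre crop to
#' `out_size x out_size`, scale to `[0, 1]` and per-channel normalisation with
#' the same constants as [train_transform()]. Consumes no randomness.
#'
#' @inheritParams train_transform
#' @return A normalised `out_size x out_size x 3` array.
#' @export
eval_transform <- function(image, out_size = 224L) {
  if (is.list(image)) image <- image$image
  check_rgb(image)
  short <- as.integer(ceiling(out_size * 8 / 7))
  img <- resize_short_side(image, short)
  d <- dim(img)
  if (d[1] < out_size || d[2] < out_size) {
    stop(sprintf("image is %dx%d after resize; cannot centre-crop %dx%d",
                 d[1], d[2], out_size, out_size))
  }
  top <- (d[1] - out_size) %/% 2 + 1L
  left <- (d[2] - out_size) %/% 2 + 1L
  img <- img[top:(top + out_size - 1L), left:(left + out_size - 1L), ,
             drop = FALSE]
  normalize_channels(img / 255)
}

#' Stratified progressive subsampling
#'
#' Draws a subset of a merged record pool for the progressive
#' dataset-extension protocol, without replacement and seeded. When `classes`
#' is `NULL` the pool is a single stratum and `floor(rate * n)` records are
#' drawn from it -- the rule behind the binary-task subset sizes
#' 817/1635/2453/3271/4089 on the full merged pool of 4089. When `classes`
#' names a record field's class labels, `floor(rate * n_c)` records are drawn
#' per class -- the rule behind the ternary-task sizes
#' 499/1000/1501/2002/2503 on the merged diseased pool (850/844/809 per
#' disease). The two rules are jointly the only simple pair reproducing every
#' printed subset size; see the methods vignette.
#'
#' @param merged List of records (e.g. validation plus test).
#' @param rate Sampling rate in (0, 1].
#' @param seed Integer seed.
#' @param classes Optional character vector: the per-record class labels to
#'   stratify on (same length as `merged`).
#' @return A list of records (a subset of `merged`).
#' @export
progressive_subset <- function(merged, rate, seed = 1L, classes = NULL) {
  if (!(rate > 0 && rate <= 1)) stop("rate must be in (0, 1]")
  n <- length(merged)
  if (n == 0) stop("merged pool is empty")
  set.seed(seed)
  if (is.null(classes)) {
    k <- floor(rate * n)
    idx <- sort(sample.int(n, k))
  } else {
    stopifnot(length(classes) == n)
    idx <- integer(0)
    for (cl in unique(classes)) {
      pos <- which(classes == cl)
      if (length(pos) == 0) stop(sprintf("empty class '%s'", cl))
      k <- floor(rate * length(pos))
      idx <- c(idx, sample(pos, k))
    }
    idx <- sort(idx)
  }
  merged[idx]
}
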