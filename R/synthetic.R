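# Seeded synthetic endoscopy-image generator. Images are reddish low-frequency
# mucosa textures with class-conditional lesion structure:
#   ulcerative colitis -> diffuse speckled dark-red patches,
#   polyps             -> bright filled ellipses with a specular highlight,
#   esophagitis        -> elongated pale streaks,
#   normal             -> base texture only.
# The class signatures are intentionally strong (documented effect sizes in the
# methods vignette) so that small models trained for minutes on a CPU can
# separate them; the generator emulates the raw-resolution range and split
# sizes of the real corpus, not its photographic appearance.

#' Synthetic dataset specification
#'
#' @param width_range,height_range Integer ranges the raw resolution is drawn
#'   from, uniformly per image. The defaults span the raw corpus range
#'   (720x576 to 1920x1072); `preset = "desk"` uses a small range suited to
#'   CPU test runs.
#' @param lesion_count_range How many lesions a diseased image carries.
#' @param lesion_radius_frac Lesion radius range as a fraction of the shorter
#'   image side.
#' @param lesion_intensity Additive lesion amplitude on the 0-255 scale; the
#'   polyp green-channel mean is raised by roughly
#'   `coverage x lesion_intensity` (about +7 at defaults), the documented
#'   effect size behind the generator's separability guarantees.
#' @param base_mean Per-channel mean of the mucosa base texture (RGB, 0-255).
#' @param texture_amplitude Amplitude of the low-frequency texture field.
#' @param noise_sd Pixel-noise standard deviation.
#' @param preset `"paper"` (default raw-resolution range) or `"desk"`
#'   (reduced resolutions for fast CPU work; nothing else changes).
#' @return A `flater_synth_spec` list.
#' @export
synthetic_spec <- function(width_range = c(720L, 1920L),
                           height_range = c(576L, 1072L),
                           lesion_count_range = c(1L, 3L),
                           lesion_radius_frac = c(0.08, 0.18),
                           lesion_intensity = 70,
                           base_mean = c(150, 90, 80),
                           texture_amplitude = 25,
                           noise_sd = 8,
                           preset = c("paper", "desk")) {
  preset <- match.arg(preset)
  if (preset == "desk") {
    width_range <- c(96L, 160L)
    height_range <- c(72L, 128L)
  }
  spec <- list(width_range = as.integer(width_range),
               height_range = as.integer(height_range),
               lesion_count_range = as.integer(lesion_count_range),
               lesion_radius_frac = lesion_radius_frac,
               lesion_intensity = lesion_intensity,
               base_mean = base_mean,
               texture_amplitude = texture_amplitude,
               noise_sd = noise_sd,
               preset = preset)
  class(spec) <- "flater_synth_spec"
  spec
}

# Low-frequency field: coarse random grid bilinearly upsampled to full size.
lowfreq_field <- function(h, w, grid = 8L) {
  g <- matrix(stats::rnorm(grid * grid), grid, grid)
  resize_bilinear(array(g, c(grid, grid, 1)), h, w)[, , 1]
}

#' Synthesise one labelled image
#'
#' Generates one raw-resolution RGB image for the given class, deterministic
#' in `seed`. Diseased classes get their lesion signature drawn on top of the
#' shared mucosa base texture; the union of lesion footprints is returned as a
#' logical mask (all-`FALSE` for normal images).
#'
#' @param class_label One of [flater_classes()].
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed for this image.
#' @return An image record: list with `image` (`H x W x 3`, values in 0..255),
#'   `binary_label` (`"normal"`/`"diseased"`), `ternary_label` (disease name
#'   or `NA`), `class`, `lesion_mask`, `width`, `height`, `seed`.
#' @export
synthesize_image <- function(class_label, spec = synthetic_spec(), seed = 1L) {
  if (!class_label %in% flater_classes()) {
    stop(sprintf("unknown class '%s'; classes: %s", class_label,
                 paste(flater_classes(), collapse = ", ")))
  }
  set.seed(seed)
  w <- sample(spec$width_range[1]:spec$width_range[2], 1)
  h <- sample(spec$height_range[1]:spec$height_range[2], 1)
  img <- array(0, c(h, w, 3))
  for (c in 1:3) {
    img[, , c] <- spec$base_mean[c] +
      spec$texture_amplitude * lowfreq_field(h, w) +
      stats::rnorm(h * w, sd = spec$noise_sd)
  }
  mask <- matrix(FALSE, h, w)

  if (class_label != "normal") {
    n_lesions <- sample(spec$lesion_count_range[1]:spec$lesion_count_range[2], 1)
    rmin <- min(h, w)
    xg <- matrix(rep(seq_len(w), each = h), h, w)
    yg <- matrix(rep(seq_len(h), w), h, w)
    amp <- spec$lesion_intensity
    for (k in seq_len(n_lesions)) {
      cx <- stats::runif(1, 0.2 * w, 0.8 * w)
      cy <- stats::runif(1, 0.2 * h, 0.8 * h)
      r <- stats::runif(1, spec$lesion_radius_frac[1],
                        spec$lesion_radius_frac[2]) * rmin
      if (class_label == "ulcerative-colitis") {
        # diffuse speckled dark-red patch: red up, green/blue down on a
        # random half of the in-lesion pixels
        inside <- ((xg - cx)^2 + (yg - cy)^2) <= (1.4 * r)^2
        speck <- inside & (matrix(stats::runif(h * w), h, w) < 0.5)
        img[, , 1][speck] <- img[, , 1][speck] + 0.6 * amp
        img[, , 2][speck] <- img[, , 2][speck] - 0.5 * amp
        img[, , 3][speck] <- img[, , 3][speck] - 0.3 * amp
        mask <- mask | inside
      } else if (class_label == "polyps") {
        # bright filled ellipse with a smaller specular highlight
        ar <- stats::runif(1, 0.7, 1.4)
        th <- stats::runif(1, 0, pi)
        xr <- (xg - cx) * cos(th) + (yg - cy) * sin(th)
        yr <- -(xg - cx) * sin(th) + (yg - cy) * cos(th)
        inside <- (xr / r)^2 + (yr / (r * ar))^2 <= 1
        core <- (xr / (0.35 * r))^2 + (yr / (0.35 * r * ar))^2 <= 1
        for (c in 1:3) {
          img[, , c][inside] <- img[, , c][inside] + amp
          img[, , c][core] <- img[, , c][core] + 0.6 * amp
        }
        mask <- mask | inside
      } else { # esophagitis: elongated pale streak
        th <- stats::runif(1, -pi / 3, pi / 3)
        xr <- (xg - cx) * cos(th) + (yg - cy) * sin(th)
        yr <- -(xg - cx) * sin(th) + (yg - cy) * cos(th)
        inside <- abs(xr) <= 2.5 * r & abs(yr) <= 0.25 * r
        for (c in 1:3) img[, , c][inside] <- img[, , c][inside] + 0.85 * amp
        mask <- mask | inside
      }
    }
  }

  img <- pmin(pmax(img, 0), 255)
  list(image = img,
       binary_label = if (class_label == "normal") "normal" else "diseased",
       ternary_label = if (class_label == "normal") NA_character_
                       else class_label,
       class = class_label,
       lesion_mask = mask,
       width = w, height = h, seed = as.integer(seed))
}

#' Default split-size template
#'
#' Per-class train/validation/test counts of the curated corpus the study
#' conditions assume: 2800/1074/512 normal, 948/598/252 ulcerative colitis,
#' 949/595/249 polyps and 948/546/263 esophagitis (9734 images in total;
#' splits of 5645/2813/1276). `scale` shrinks every cell with `floor`
#' (minimum 1) for desk-scale work.
#'
#' @param scale Multiplier in (0, 1].
#' @return A data frame with columns `class`, `train`, `validation`, `test`.
#' @export
split_template <- function(scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  tpl <- data.frame(
    class = flater_classes(),
    train = c(2800L, 948L, 949L, 948L),
    validation = c(1074L, 598L, 595L, 546L),
    test = c(512L, 252L, 249L, 263L),
    stringsAsFactors = FALSE
  )
  if (scale < 1) {
    for (cn in c("train", "validation", "test")) {
      tpl[[cn]] <- pmax(1L, as.integer(floor(scale * tpl[[cn]])))
    }
  }
  tpl
}

#' Synthesise a full dataset
#'
#' Draws disjoint, individually seeded image records for the train, validation
#' and test splits according to a per-class split-size table, and builds a
#' manifest. Records carry their own seeds, so images can be generated lazily
#' (`materialize = FALSE` stores only metadata; [record_image()] regenerates
#' the pixels on demand, byte-identically).
#'
#' @param spec A [synthetic_spec()].
#' @param split_sizes Data frame as returned by [split_template()].
#' @param seed Master seed; all record seeds derive from it.
#' @param materialize Keep the pixel arrays in the records (default `TRUE`;
#'   use `FALSE` for size bookkeeping at full template scale).
#' @return A list with `train`, `validation`, `test` (each a list with `name`
#'   and `records`), the `manifest` data frame, `spec` and `seed`.
#' @export
synthesize_dataset <- function(spec = synthetic_spec(),
                               split_sizes = split_template(),
                               seed = 1L,
                               materialize = TRUE) {
  stopifnot(all(c("class", "train", "validation", "test") %in%
                  names(split_sizes)))
  if (any(split_sizes$train < 0 | split_sizes$validation < 0 |
            split_sizes$test < 0)) {
    stop("split sizes must be non-negative")
  }
  total <- sum(split_sizes$train) + sum(split_sizes$validation) +
    sum(split_sizes$test)
  set.seed(seed)
  record_seeds <- sample.int(.Machine$integer.max - 1L, total)

  splits <- list()
  manifest <- list()
  idx <- 0L
  for (split_name in c("train", "validation", "test")) {
    records <- list()
    for (r in seq_len(nrow(split_sizes))) {
      cls <- split_sizes$class[r]
      n <- split_sizes[[split_name]][r]
      for (k in seq_len(n)) {
        idx <- idx + 1L
        rs <- record_seeds[idx]
        if (materialize) {
          rec <- synthesize_image(cls, spec, seed = rs)
        } else {
          set.seed(rs)
          w <- sample(spec$width_range[1]:spec$width_range[2], 1)
          h <- sample(spec$height_range[1]:spec$height_range[2], 1)
          rec <- list(image = NULL,
                      binary_label = if (cls == "normal") "normal"
                                     else "diseased",
                      ternary_label = if (cls == "normal") NA_character_
                                      else cls,
                      class = cls, lesion_mask = NULL,
                      width = w, height = h, seed = rs)
        }
        rec$id <- sprintf("%s-%06d", split_name, length(records) + 1L)
        rec$split <- split_name
        records[[length(records) + 1L]] <- rec
      }
    }
    splits[[split_name]] <- list(name = split_name, records = records)
    manifest[[split_name]] <- data.frame(
      id = vapply(records, `[[`, "", "id"),
      split = split_name,
      class = vapply(records, `[[`, "", "class"),
      binary_label = vapply(records, `[[`, "", "binary_label"),
      ternary_label = vapply(records, `[[`, "", "ternary_label"),
      width = vapply(records, `[[`, 0L, "width"),
      height = vapply(records, `[[`, 0L, "height"),
      seed = vapply(records, `[[`, 0L, "seed"),
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  list(train = splits$train, validation = splits$validation,
       test = splits$test, manifest = manifest, spec = spec,
       seed = as.integer(seed))
}

#' Regenerate a record's pixels
#'
#' @param record A record from [synthesize_dataset()] (materialised or not).
#' @param spec The [synthetic_spec()] the dataset was generated with.
#' @return The record with `image` and `lesion_mask` filled in.
#' @export
record_image <- function(record, spec) {
  if (!is.null(record$image)) return(record)
  rec <- synthesize_image(record$class, spec, seed = record$seed)
  record$image <- rec$image
  record$lesion_mask <- rec$lesion_mask
  record
}

#' Digest of a dataset manifest
#'
#' MD5 of the manifest's CSV serialisation; a pure function of
#' `(spec, split_sizes, seed)`, used to assert generator determinism.
#'
#' @param manifest The manifest data frame from [synthesize_dataset()].
#' @return A hex digest string.
#' @export
manifest_digest <- function(manifest) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  utils::write.csv(manifest, f, row.names = FALSE)
  unname(tools::md5sum(f))
}

#' Write a dataset to disk
#'
#' Exports records as PNG files in a class-per-folder layout
#' (`<split>/<class>/<id>.png`) together with a manifest CSV
#' (`manifest.csv`, columns `path, split, binary_label, ternary_label, ...`).
#'
#' @param ds A dataset from [synthesize_dataset()].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(ds$manifest))
  i <- 0L
  for (split_name in c("train", "validation", "test")) {
    for (rec in ds[[split_name]]$records) {
      i <- i + 1L
      rec <- record_image(rec, ds$spec)
      sub <- file.path(dir, split_name, rec$class)
      dir.create(sub, recursive = TRUE, showWarnings = FALSE)
      p <- file.path(sub, paste0(rec$id, ".png"))
      png::writePNG(rec$image / 255, p)
      paths[i] <- p
    }
  }
  man <- ds$manifest
  man$path <- paths
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mf, row.names = FALSE)
  invisible(mf)
}

#' Read a dataset from a manifest CSV
#'
#' Loads PNG images listed in a manifest written by [write_dataset()] back
#' into the in-memory dataset layout.
#'
#' @param manifest_path Path to `manifest.csv`.
#' @return A dataset list (`train`/`validation`/`test` + `manifest`).
#' @export
read_dataset <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  splits <- list()
  for (split_name in c("train", "validation", "test")) {
    rows <- man[man$split == split_name, , drop = FALSE]
    records <- lapply(seq_len(nrow(rows)), function(i) {
      p <- rows$path[i]
      if (!file.exists(p)) p <- file.path(base, p)
      img <- png::readPNG(p) * 255
      list(image = img, binary_label = rows$binary_label[i],
           ternary_label = if (is.na(rows$ternary_label[i]) ||
                                 rows$ternary_label[i] == "") NA_character_
                           else rows$ternary_label[i],
           class = rows$class[i], lesion_mask = NULL,
           width = ncol(img), height = nrow(img),
           seed = rows$seed[i], id = rows$id[i], split = split_name)
    })
    splits[[split_name]] <- list(name = split_name, records = records)
  }
  list(train = splits$train, validation = splits$validation,
       test = splits$test, manifest = man)
}
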