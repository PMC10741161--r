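# Joint training of the shared backbone with both heads. The loss is
#   w_bin * CE(binary head) + w_ter * CE(ternary head over diseased samples)
# with the ternary term averaged only over samples whose ground truth is
# diseased; a batch without diseased samples contributes the binary term only.

#' Training configuration
#'
#' @param epochs Number of passes over the training split.
#' @param batch_size Mini-batch size.
#' @param learning_rate AdamW step size.
#' @param weight_decay Decoupled weight decay (applied to matrices/tensors,
#'   not to biases or normalisation parameters).
#' @param optimizer Only `"adamw"` is implemented.
#' @param lr_schedule `"cosine"` (decay to 0 over the epochs) or `"constant"`.
#' @param w_bin,w_ter Non-negative loss weights of the two heads (not both 0).
#' @param seed Seed controlling shuffling, augmentation and dropout.
#' @param augment Re-augment the training images each epoch with
#'   [train_transform()]; when `FALSE` a single deterministic
#'   [eval_transform()] pass is used (fast desk-scale mode).
#' @return A `flater_train_config` list.
#' @export
train_config <- function(epochs = 10L, batch_size = 32L,
                         learning_rate = 1e-4, weight_decay = 1e-4,
                         optimizer = "adamw",
                         lr_schedule = c("cosine", "constant"),
                         w_bin = 1, w_ter = 1, seed = 1L,
                         augment = TRUE) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            weight_decay >= 0, w_bin >= 0, w_ter >= 0)
  if (w_bin == 0 && w_ter == 0) stop("w_bin and w_ter cannot both be 0")
  if (optimizer != "adamw") stop("only the 'adamw' optimizer is implemented")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay, optimizer = optimizer,
                 lr_schedule = lr_schedule, w_bin = w_bin, w_ter = w_ter,
                 seed = as.integer(seed), augment = isTRUE(augment)),
            class = "flater_train_config")
}

# Encode labels to head indices. binary: normal = 1, diseased = 2.
# ternary: disease_classes() order.
binary_index <- function(labels) {
  match(labels, binary_classes())
}

ternary_index <- function(labels) {
  match(labels, disease_classes())
}

#' Joint two-head cross-entropy loss
#'
#' @param output A list with `binary_logits` (`B x 2`) and `ternary_logits`
#'   (`B x 3`) as returned by [model_forward()].
#' @param binary_labels Character vector (`"normal"`/`"diseased"`) of length
#'   `B`.
#' @param ternary_labels Character vector of disease names, `NA` for normal
#'   samples. Supplying a disease label for a normal sample is an error.
#' @param w_bin,w_ter Loss weights.
#' @return A list: `total`, `binary`, `ternary` (mean cross-entropies; the
#'   ternary component is 0 when the batch has no diseased samples) and
#'   `n_diseased`.
#' @export
joint_loss <- function(output, binary_labels, ternary_labels,
                       w_bin = 1, w_ter = 1) {
  B <- nrow(output$binary_logits)
  stopifnot(length(binary_labels) == B, length(ternary_labels) == B)
  bad <- binary_labels == "normal" & !is.na(ternary_labels)
  if (any(bad)) {
    stop(sprintf("%d normal sample(s) carry a ternary label", sum(bad)))
  }
  yb <- binary_index(binary_labels)
  if (anyNA(yb)) stop("unknown binary label")
  lsb <- row_log_softmax(output$binary_logits)
  l_bin <- -mean(lsb[cbind(seq_len(B), yb)])

  dis <- which(binary_labels == "diseased")
  if (length(dis) > 0) {
    yt <- ternary_index(ternary_labels[dis])
    if (anyNA(yt)) stop("diseased sample without a valid ternary label")
    lst <- row_log_softmax(output$ternary_logits[dis, , drop = FALSE])
    l_ter <- -mean(lst[cbind(seq_along(dis), yt)])
  } else {
    l_ter <- 0
  }
  list(total = w_bin * l_bin + w_ter * l_ter,
       binary = l_bin, ternary = l_ter, n_diseased = length(dis))
}

# Loss gradients w.r.t. the two logit matrices (mean-reduced as in joint_loss).
joint_loss_grads <- function(output, binary_labels, ternary_labels,
                             w_bin, w_ter) {
  B <- nrow(output$binary_logits)
  yb <- binary_index(binary_labels)
  pb <- row_softmax(output$binary_logits)
  dbin <- pb
  dbin[cbind(seq_len(B), yb)] <- dbin[cbind(seq_len(B), yb)] - 1
  dbin <- dbin * (w_bin / B)

  dter <- matrix(0, B, ncol(output$ternary_logits))
  dis <- which(binary_labels == "diseased")
  if (length(dis) > 0 && w_ter > 0) {
    yt <- ternary_index(ternary_labels[dis])
    pt <- row_softmax(output$ternary_logits[dis, , drop = FALSE])
    pt[cbind(seq_along(dis), yt)] <- pt[cbind(seq_along(dis), yt)] - 1
    dter[dis, ] <- pt * (w_ter / length(dis))
  }
  list(dbin = dbin, dter = dter)
}

## ---- AdamW ------------------------------------------------------------------

adamw_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

# One decoupled-weight-decay Adam step over the parameter tree. Weight decay
# is applied only to parameters with >= 2 dimensions (weights, not biases or
# norm gains/shifts).
adamw_step <- function(params, grads, state, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    step <- lr * (m / bc1) / (sqrt(v / bc2) + eps)
    if (wd > 0 && !is.null(dim(p)) && length(dim(p)) >= 2) {
      step <- step + lr * wd * p
    }
    list(p = p - step, m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

## ---- fit --------------------------------------------------------------------

any_nonfinite <- function(x) {
  if (is.list(x)) any(vapply(x, any_nonfinite, logical(1))) else !all(is.finite(x))
}

#' Train a model
#'
#' Mini-batch AdamW optimisation of the joint two-head loss, with per-epoch
#' validation metrics and best-checkpoint retention (highest validation macro
#' F1, averaged over the binary F1 and the ternary macro F1). Fully seeded:
#' two runs with the same model, data and config are bitwise identical.
#'
#' @param model A freshly built or previously trained `flater_model`.
#' @param splits A dataset as from [synthesize_dataset()] (needs `train` and
#'   `validation`); lazy records are materialised via `spec`.
#' @param config A [train_config()].
#' @param spec The [synthetic_spec()] used when records are lazy.
#' @return A list: `model` (best validation checkpoint), `final_model` (last
#'   epoch), `history` (one row per epoch: losses and validation metrics).
#' @export
fit <- function(model, splits, config = train_config(), spec = NULL) {
  stopifnot(inherits(model, "flater_model"),
            inherits(config, "flater_train_config"))
  set.seed(config$seed)
  size <- model$config$image_size

  get_image <- function(rec) {
    if (is.null(rec$image)) {
      if (is.null(spec)) stop("lazy records need `spec` to materialise")
      rec <- record_image(rec, spec)
    }
    rec
  }
  train_recs <- lapply(splits$train$records, get_image)
  val_recs <- lapply(splits$validation$records, get_image)
  n <- length(train_recs)
  if (n == 0) stop("empty training split")

  ybin <- vapply(train_recs, `[[`, "", "binary_label")
  yter <- vapply(train_recs, `[[`, "", "ternary_label")

  # evaluation tensors are fixed; training tensors are re-augmented per epoch
  # unless augment = FALSE
  val_x <- lapply(val_recs, function(r) eval_transform(r$image, size))
  plain_x <- NULL
  if (!config$augment) {
    plain_x <- lapply(train_recs, function(r) eval_transform(r$image, size))
  }

  history <- data.frame()
  frozen <- list(head_ter = model$params$head_ter,
                 head_bin = model$params$head_bin)
  best <- list(score = -Inf, model = model)
  steps_total <- config$epochs * ceiling(n / config$batch_size)
  opt <- adamw_init(model$params)
  step <- 0L

  for (epoch in seq_len(config$epochs)) {
    xs <- if (config$augment) {
      lapply(train_recs, function(r) train_transform(r$image, size))
    } else plain_x
    ord <- sample.int(n)
    ep_loss <- 0; ep_bin <- 0; ep_ter <- 0; nb <- 0L
    correct_bin <- 0L

    for (start in seq(1, n, by = config$batch_size)) {
      ids <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- as_batch(xs[ids])
      ff <- model_forward_full(model, xb, training = TRUE)
      model$buffers <- ff$buffers
      loss <- joint_loss(ff$out, ybin[ids], yter[ids],
                         config$w_bin, config$w_ter)
      if (!is.finite(loss$total)) {
        stop(sprintf(
          "non-finite loss at epoch %d (binary %.4g, ternary %.4g); aborting",
          epoch, loss$binary, loss$ternary))
      }
      gl <- joint_loss_grads(ff$out, ybin[ids], yter[ids],
                             config$w_bin, config$w_ter)
      grads <- model_backward(model, ff$cache, gl$dbin, gl$dter)
      if (any_nonfinite(grads)) stop("non-finite gradient; aborting")

      step <- step + 1L
      lr <- if (config$lr_schedule == "cosine") {
        config$learning_rate * 0.5 * (1 + cos(pi * (step - 1) / steps_total))
      } else config$learning_rate
      upd <- adamw_step(model$params, grads, opt, lr, config$weight_decay)
      model$params <- upd$params
      opt <- upd$state
      # a head with zero loss weight receives no gradient; keep it frozen
      # (weight decay must not silently shrink an untrained head)
      if (config$w_ter == 0) model$params$head_ter <- frozen$head_ter
      if (config$w_bin == 0) model$params$head_bin <- frozen$head_bin

      ep_loss <- ep_loss + loss$total
      ep_bin <- ep_bin + loss$binary
      ep_ter <- ep_ter + loss$ternary
      nb <- nb + 1L
      pred <- max.col(ff$out$binary_logits)
      correct_bin <- correct_bin + sum(pred == binary_index(ybin[ids]))
    }

    vm <- validation_metrics(model, val_recs, val_x)
    history <- rbind(history, data.frame(
      epoch = epoch, loss = ep_loss / nb, loss_bin = ep_bin / nb,
      loss_ter = ep_ter / nb, train_binary_acc = correct_bin / n,
      val_binary_acc = vm$bin_acc, val_binary_f1 = vm$bin_f1,
      val_ternary_acc = vm$ter_acc, val_ternary_f1 = vm$ter_f1,
      val_macro_f1 = vm$macro_f1))
    if (vm$macro_f1 > best$score) {
      best <- list(score = vm$macro_f1, model = model)
    }
  }
  list(model = best$model, final_model = model, history = history)
}

# Quick validation metrics during training (accuracy + macro F1 per task).
validation_metrics <- function(model, records, tensors, batch_size = 64L) {
  preds <- predict_records(model, tensors, batch_size)
  ybin <- vapply(records, `[[`, "", "binary_label")
  pb <- binary_classes()[max.col(preds$binary_logits)]
  cm_b <- confusion(pb, ybin, binary_classes())
  mb <- suppressWarnings(compute_metrics(cm_b, positive_class = "diseased"))
  dis <- which(ybin == "diseased")
  if (length(dis) > 0) {
    yt <- vapply(records[dis], `[[`, "", "ternary_label")
    pt <- disease_classes()[
      max.col(preds$ternary_logits[dis, , drop = FALSE])]
    cm_t <- confusion(pt, yt, disease_classes())
    mt <- suppressWarnings(compute_metrics(cm_t))
    ter_acc <- mt$accuracy; ter_f1 <- mt$f1
  } else {
    ter_acc <- NA_real_; ter_f1 <- 0
  }
  list(bin_acc = mb$accuracy, bin_f1 = mb$f1,
       ter_acc = ter_acc, ter_f1 = ter_f1,
       macro_f1 = mean(c(mb$f1, ter_f1)))
}

# Batched inference over a list of preprocessed tensors.
predict_records <- function(model, tensors, batch_size = 64L) {
  n <- length(tensors)
  bl <- matrix(0, n, model$config$n_binary)
  tl <- matrix(0, n, model$config$n_ternary)
  for (start in seq(1, n, by = batch_size)) {
    ids <- start:min(start + batch_size - 1L, n)
    out <- model_forward(model, as_batch(tensors[ids]), training = FALSE)
    bl[ids, ] <- out$binary_logits
    tl[ids, ] <- out$ternary_logits
  }
  list(binary_logits = bl, ternary_logits = tl)
}
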