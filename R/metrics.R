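# Confusion-matrix accounting and the derived metrics:
#   precision = TP/(TP+FP), recall = TP/(TP+FN),
#   accuracy = (TP+TN)/total, F1 = 2pr/(p+r),
# macro-averaged one-vs-rest for K > 2, plus threshold-sweep ROC/AUC. The
# binary positive class is "diseased" throughout: it is the unique choice
# under which the published test confusion counts (TP 749, FP 28, FN 15,
# TN 484) reproduce the reported precision/recall pair.

#' Confusion matrix
#'
#' @param pred,truth Character vectors of predicted and true labels.
#' @param classes Class vocabulary (row/column order).
#' @return A `flater_confusion` object: a `K x K` integer matrix, rows = true
#'   class, columns = predicted class.
#' @export
confusion <- function(pred, truth, classes) {
  stopifnot(length(pred) == length(truth))
  unknown <- setdiff(unique(c(pred, truth)), classes)
  if (length(unknown)) {
    stop(sprintf("unknown label(s): %s", paste(unknown, collapse = ", ")))
  }
  m <- table(factor(truth, levels = classes),
             factor(pred, levels = classes))
  m <- matrix(as.integer(m), length(classes), length(classes),
              dimnames = list(truth = classes, predicted = classes))
  structure(list(matrix = m, classes = classes, n = length(truth)),
            class = "flater_confusion")
}

#' @export
print.flater_confusion <- function(x, ...) {
  cat(sprintf("<confusion matrix> %d samples, accuracy %.4f\n", x$n,
              sum(diag(x$matrix)) / x$n))
  print(x$matrix)
  invisible(x)
}

#' Metrics from a confusion matrix
#'
#' For two classes, `positive_class` selects the class whose TP/FP/FN define
#' precision and recall. For more classes, per-class one-vs-rest metrics are
#' computed and macro-averaged (unweighted mean). A zero denominator yields 0
#' with a warning.
#'
#' @param cm A [confusion()] object.
#' @param positive_class Required when `cm` has exactly two classes.
#' @return A `flater_metrics` list: `accuracy`, `precision`, `recall`, `f1`,
#'   plus `per_class` (data frame) when K > 2.
#' @export
compute_metrics <- function(cm, positive_class = NULL) {
  stopifnot(inherits(cm, "flater_confusion"))
  m <- cm$matrix
  K <- nrow(m)
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  acc <- sum(diag(m)) / total

  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s has zero denominator; returning 0", what))
      return(0)
    }
    num / den
  }
  one_vs_rest <- function(k) {
    tp <- m[k, k]
    fp <- sum(m[-k, k])
    fn <- sum(m[k, -k])
    p <- safe_div(tp, tp + fp, sprintf("precision[%s]", cm$classes[k]))
    r <- safe_div(tp, tp + fn, sprintf("recall[%s]", cm$classes[k]))
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f1)
  }

  if (K == 2) {
    if (is.null(positive_class)) {
      stop("positive_class is required for a 2-class confusion matrix")
    }
    k <- match(positive_class, cm$classes)
    if (is.na(k)) stop(sprintf("'%s' is not a class of this matrix",
                               positive_class))
    s <- one_vs_rest(k)
    out <- list(accuracy = acc, precision = unname(s["precision"]),
                recall = unname(s["recall"]), f1 = unname(s["f1"]),
                positive_class = positive_class)
  } else {
    per <- t(vapply(seq_len(K), one_vs_rest, numeric(3)))
    per_df <- data.frame(class = cm$classes, per, stringsAsFactors = FALSE)
    out <- list(accuracy = acc,
                precision = mean(per[, "precision"]),
                recall = mean(per[, "recall"]),
                f1 = mean(per[, "f1"]),
                per_class = per_df)
  }
  class(out) <- "flater_metrics"
  out
}

#' @export
print.flater_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps every unique score as a threshold, collects (FPR, TPR) points and
#' integrates with the trapezoidal rule. For a multiclass task use one call
#' per class (one-vs-rest) and average the AUCs.
#'
#' @param scores Numeric vector of positive-class scores/probabilities.
#' @param truth Character (or logical) vector of true labels.
#' @param positive_class The label counted as positive.
#' @return A `flater_roc` list: `points` (data frame `threshold`, `fpr`,
#'   `tpr`, monotone from (0,0) to (1,1)) and `auc`.
#' @export
roc_curve_and_auc <- function(scores, truth, positive_class) {
  stopifnot(length(scores) == length(truth))
  pos <- truth == positive_class
  nP <- sum(pos)
  nN <- sum(!pos)
  if (nP == 0 || nN == 0) {
    stop("AUC undefined: truth contains a single class")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  # cumulative counts at each distinct threshold (ties collapsed)
  keep <- c(diff(s) != 0, TRUE)
  tpr <- c(0, cumsum(p)[keep] / nP)
  fpr <- c(0, cumsum(!p)[keep] / nN)
  thr <- c(Inf, s[keep])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "flater_roc")
}

#' @export
print.flater_roc <- function(x, ...) {
  cat(sprintf("<ROC> %d points, AUC %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

softmax_probs <- function(logits) exp(row_log_softmax(logits))

#' Evaluate a model on a split
#'
#' Runs the deterministic evaluation transform and a forward pass over every
#' record, then scores the requested task. The binary task uses
#' `"diseased"` as the positive class. The ternary task evaluates on the
#' ground-truth diseased records only (default) or, with
#' `cascade = TRUE`, on the records the binary head flags as diseased (the
#' deployment-style cascade); its AUC is the unweighted mean of the three
#' one-vs-rest AUCs.
#'
#' @param model A `flater_model`.
#' @param split A split (list with `records`) or a plain list of records.
#' @param task `"binary"` or `"ternary"`.
#' @param spec Optional [synthetic_spec()] to materialise lazy records.
#' @param cascade Ternary task only: gate on the binary head's predictions
#'   instead of ground truth.
#' @return A list: `metrics` ([compute_metrics()] output), `confusion`,
#'   `roc` (binary: one curve; ternary: per-class list plus `auc` mean),
#'   `n` evaluated samples.
#' @export
evaluate_model <- function(model, split, task = c("binary", "ternary"),
                           spec = NULL, cascade = FALSE) {
  task <- match.arg(task)
  records <- if (!is.null(split$records)) split$records else split
  if (length(records) == 0) stop("empty split")
  records <- lapply(records, function(r) {
    if (is.null(r$image)) {
      if (is.null(spec)) stop("lazy records need `spec` to materialise")
      record_image(r, spec)
    } else r
  })
  size <- model$config$image_size
  tensors <- lapply(records, function(r) eval_transform(r$image, size))
  preds <- predict_records(model, tensors)
  ybin <- vapply(records, `[[`, "", "binary_label")

  if (task == "binary") {
    probs <- softmax_probs(preds$binary_logits)[, 2]  # P(diseased)
    phat <- binary_classes()[(probs >= 0.5) + 1L]
    cm <- confusion(phat, ybin, binary_classes())
    metrics <- compute_metrics(cm, positive_class = "diseased")
    roc <- roc_curve_and_auc(probs, ybin, "diseased")
    metrics$auc <- roc$auc
    return(list(metrics = metrics, confusion = cm, roc = roc,
                n = length(records)))
  }

  idx <- if (cascade) {
    which(max.col(preds$binary_logits) == 2L)
  } else {
    which(ybin == "diseased")
  }
  if (length(idx) == 0) stop("no diseased samples to evaluate the ternary task")
  truth <- vapply(records[idx], function(r) {
    if (is.na(r$ternary_label)) "normal" else r$ternary_label
  }, "")
  if (cascade && any(truth == "normal")) {
    # false positives of the binary gate have no disease label; they are
    # scored as errors against every disease class by keeping them in the
    # pool with their own "normal" row
    classes <- c(disease_classes(), "normal")
  } else {
    classes <- disease_classes()
  }
  probs <- softmax_probs(preds$ternary_logits[idx, , drop = FALSE])
  phat <- disease_classes()[max.col(probs)]
  cm <- confusion(phat, truth, classes)
  metrics <- compute_metrics(cm)
  rocs <- list()
  aucs <- numeric(0)
  for (k in seq_along(disease_classes())) {
    cl <- disease_classes()[k]
    if (length(unique(truth == cl)) == 2) {
      rocs[[cl]] <- roc_curve_and_auc(probs[, k], truth, cl)
      aucs <- c(aucs, rocs[[cl]]$auc)
    }
  }
  metrics$auc <- if (length(aucs)) mean(aucs) else NA_real_
  list(metrics = metrics, confusion = cm,
       roc = list(per_class = rocs, auc = metrics$auc),
       n = length(idx))
}

#' Progressive dataset-extension evaluation
#'
#' Evaluates a fixed model on growing fractions of a merged record pool
#' (typically validation plus test). Binary task: `floor(rate * n)` records
#' from the whole pool. Ternary task: the pool is first restricted to
#' diseased records and sampled per disease class with `floor(rate * n_c)`.
#' See [progressive_subset()] for why the two rules differ.
#'
#' @param model A `flater_model`.
#' @param merged List of records (validation plus test).
#' @param rates Sampling rates, default `c(0.2, 0.4, 0.6, 0.8, 1)`.
#' @param seed Subsampling seed.
#' @param task `"binary"` or `"ternary"`.
#' @param spec Optional spec for lazy records.
#' @return A data frame with one row per rate: `rate`, `quantity`,
#'   `accuracy`, `precision`, `recall`, `f1`, `auc`.
#' @export
progressive_evaluation <- function(model, merged,
                                   rates = c(0.2, 0.4, 0.6, 0.8, 1),
                                   seed = 1L, task = c("binary", "ternary"),
                                   spec = NULL) {
  task <- match.arg(task)
  stopifnot(all(rates > 0 & rates <= 1))
  if (task == "ternary") {
    keep <- vapply(merged, `[[`, "", "binary_label") == "diseased"
    merged <- merged[keep]
  }
  out <- data.frame()
  for (i in seq_along(rates)) {
    r <- rates[i]
    classes <- if (task == "ternary") {
      vapply(merged, `[[`, "", "ternary_label")
    } else NULL
    sub <- progressive_subset(merged, r, seed = seed + i - 1L,
                              classes = classes)
    ev <- evaluate_model(model, sub, task = task, spec = spec)
    out <- rbind(out, data.frame(
      rate = r, quantity = ev$n, accuracy = ev$metrics$accuracy,
      precision = ev$metrics$precision, recall = ev$metrics$recall,
      f1 = ev$metrics$f1, auc = ev$metrics$auc))
  }
  out
}

#' Ablation study driver
#'
#' Trains all four architecture variants (full, without residual stem,
#' without spatial attention, bare ViT backbone) under an identical training
#' budget and seed, and evaluates each on the validation and test splits for
#' both tasks.
#'
#' @param config A [flater_config()].
#' @param splits A dataset (train/validation/test).
#' @param tconfig A [train_config()].
#' @param spec Optional spec for lazy records.
#' @return A data frame: one row per variant x task x split with the metric
#'   columns and the variant's trainable-parameter count.
#' @export
ablation_study <- function(config, splits, tconfig, spec = NULL) {
  out <- data.frame()
  for (v in FLATER_VARIANTS) {
    model <- make_ablation_variant(config, v, seed = tconfig$seed)
    n_par <- count_trainable_parameters(model)
    fitres <- fit(model, splits, tconfig, spec = spec)
    for (task in c("binary", "ternary")) {
      for (split_name in c("validation", "test")) {
        ev <- evaluate_model(fitres$model, splits[[split_name]], task = task,
                             spec = spec)
        out <- rbind(out, data.frame(
          variant = v, task = task, split = split_name,
          accuracy = ev$metrics$accuracy, precision = ev$metrics$precision,
          recall = ev$metrics$recall, f1 = ev$metrics$f1,
          auc = ev$metrics$auc, parameters = n_par))
      }
    }
  }
  out
}

#' Stem saliency map
#'
#' Channel-aggregated absolute activation of the residual stem's output,
#' min-max scaled to `[0, 1]`, at the model's input resolution -- a view of
#' which image regions the local-feature extractor responds to.
#'
#' @param model A `flater_model` with a residual stem.
#' @param image A preprocessed `image_size x image_size x 3` array.
#' @return An `image_size x image_size` matrix with values in `[0, 1]`.
#' @export
saliency_map <- function(model, image) {
  f1 <- stem_forward(image, model, training = FALSE)
  s <- apply(abs(f1), c(1, 2), mean)
  rng <- range(s)
  if (rng[2] - rng[1] < 1e-12) {
    return(matrix(0, nrow(s), ncol(s)))
  }
  (s - rng[1]) / (rng[2] - rng[1])
}

#' Export a metrics report
#'
#' Writes a metrics/confusion/ROC report to CSV and JSON files.
#'
#' @param ev Output of [evaluate_model()].
#' @param prefix Path prefix; files `<prefix>_metrics.json`,
#'   `<prefix>_confusion.csv` and (binary task) `<prefix>_roc.csv` are
#'   written.
#' @return The metrics JSON path, invisibly.
#' @export
export_report <- function(ev, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  mx <- ev$metrics
  jsonlite::write_json(
    list(accuracy = mx$accuracy, precision = mx$precision,
         recall = mx$recall, f1 = mx$f1, auc = mx$auc, n = ev$n),
    paste0(prefix, "_metrics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(ev$confusion$matrix),
                   paste0(prefix, "_confusion.csv"))
  if (inherits(ev$roc, "flater_roc")) {
    utils::write.csv(ev$roc$points, paste0(prefix, "_roc.csv"),
                     row.names = FALSE)
  }
  invisible(paste0(prefix, "_metrics.json"))
}
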