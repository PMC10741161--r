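test_that("confusion matrix matches hand enumeration", {
  pred <- c("a", "a", "b", "b", "b", "a")
  truth <- c("a", "b", "b", "b", "a", "a")
  cm <- confusion(pred, truth, c("a", "b"))
  expect_equal(unname(cm$matrix), matrix(c(2, 1, 1, 2), 2, byrow = TRUE))
  expect_equal(sum(cm$matrix) - sum(diag(cm$matrix)), 2)
  all_right <- confusion(truth, truth, c("a", "b"))
  expect_equal(unname(all_right$matrix), diag(c(3, 3)))
  expect_error(confusion(c("a", "x"), c("a", "b"), c("a", "b")), "unknown")
})

test_that("published binary test counts map to the published metrics", {
  # TP 749, FP 28, FN 15, TN 484 with positive class = diseased
  truth <- c(rep("diseased", 764), rep("normal", 512))
  pred <- c(rep("diseased", 749), rep("normal", 15),
            rep("diseased", 28), rep("normal", 484))
  cm <- confusion(pred, truth, binary_classes())
  m <- compute_metrics(cm, positive_class = "diseased")
  expect_equal(cm$n, 1276)
  expect_equal(sum(cm$matrix) - sum(diag(cm$matrix)), 43)
  expect_equal(round(m$accuracy, 4), 0.9663)
  expect_equal(round(m$precision, 4), 0.9640)
  expect_equal(round(m$recall, 4), 0.9804)
  expect_equal(round(m$f1, 4), 0.9721)
  # the opposite positive class does NOT reproduce the published pair:
  # "diseased" is the unique consistent choice
  m2 <- compute_metrics(cm, positive_class = "normal")
  expect_false(round(m2$precision, 4) == 0.9640)
  expect_false(round(m2$recall, 4) == 0.9804)
})

test_that("metric identities hold for arbitrary count matrices", {
  set.seed(31)
  for (i in 1:20) {
    K <- sample(2:4, 1)
    mat <- matrix(rpois(K * K, 8), K, K)
    classes <- letters[1:K]
    truth <- rep(rep(classes, each = K), times = as.vector(t(mat)))
    pred <- rep(rep(classes, K), times = as.vector(t(mat)))
    cm <- confusion(pred, truth, classes)
    expect_equal(unname(cm$matrix), mat)
    m <- suppressWarnings(
      compute_metrics(cm, positive_class = if (K == 2) classes[1] else NULL))
    expect_equal(m$accuracy, 1 - (sum(mat) - sum(diag(mat))) / sum(mat))
    # brute-force one-vs-rest tally oracle
    for (k in seq_len(K)) {
      tp <- sum(pred == classes[k] & truth == classes[k])
      fp <- sum(pred == classes[k] & truth != classes[k])
      fn <- sum(pred != classes[k] & truth == classes[k])
      p <- if (tp + fp == 0) 0 else tp / (tp + fp)
      r <- if (tp + fn == 0) 0 else tp / (tp + fn)
      f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
      if (K == 2 && k == 1) {
        expect_equal(m$precision, p)
        expect_equal(m$recall, r)
      } else if (K > 2) {
        expect_equal(m$per_class$f1[k], f1)
      }
    }
    if (K > 2) {
      expect_gte(m$f1, min(m$per_class$f1))
      expect_lte(m$f1, max(m$per_class$f1))
    }
  }
})

test_that("perfect and degenerate confusion matrices behave as specified", {
  truth <- rep(disease_classes(), times = c(3, 4, 5))
  cm <- confusion(truth, truth, disease_classes())
  m <- compute_metrics(cm)
  expect_equal(unname(unlist(m[c("accuracy", "precision", "recall", "f1")])),
               rep(1, 4))
  # zero denominator -> 0 with a warning
  cm0 <- confusion(rep("a", 4), c("a", "a", "b", "b"), c("a", "b"))
  expect_warning(m0 <- compute_metrics(cm0, positive_class = "b"),
                 "zero denominator")
  expect_equal(m0$precision, 0)
})

test_that("trapezoidal AUC equals the pairwise-ordering probability", {
  set.seed(41)
  for (i in 1:10) {
    n <- 20
    scores <- round(runif(n), 2)   # ties likely
    truth <- sample(c("pos", "neg"), n, replace = TRUE,
                    prob = c(0.5, 0.5))
    if (length(unique(truth)) < 2) truth[1:2] <- c("pos", "neg")
    roc <- roc_curve_and_auc(scores, truth, "pos")
    pos <- which(truth == "pos"); neg <- which(truth == "neg")
    pairs <- expand.grid(p = pos, q = neg)
    mw <- mean(ifelse(scores[pairs$p] > scores[pairs$q], 1,
                      ifelse(scores[pairs$p] == scores[pairs$q], 0.5, 0)))
    expect_equal(roc$auc, mw, tolerance = 1e-12)
    expect_equal(roc$points$fpr[1], 0)
    expect_equal(roc$points$tpr[1], 0)
    expect_equal(utils::tail(roc$points$fpr, 1), 1)
    expect_equal(utils::tail(roc$points$tpr, 1), 1)
    expect_true(all(diff(roc$points$fpr) >= 0))
    expect_true(all(diff(roc$points$tpr) >= 0))
  }
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  scores <- runif(50)
  truth <- sample(c("pos", "neg"), 50, replace = TRUE)
  got <- roc_curve_and_auc(scores, truth, "pos")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores,
                                        levels = c("neg", "pos"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("AUC boundary cases: perfect separation, ties, single class", {
  truth <- c(rep("pos", 5), rep("neg", 5))
  expect_equal(roc_curve_and_auc(c(6:10, 1:5), truth, "pos")$auc, 1)
  expect_equal(roc_curve_and_auc(rep(0.5, 10), truth, "pos")$auc, 0.5)
  expect_error(roc_curve_and_auc(runif(5), rep("pos", 5), "pos"),
               "single class")
})

test_that("evaluation protocols count and score the right samples", {
  ds <- desk_dataset()
  m <- flater_model(micro_config(), seed = 1)
  ev_b <- suppressWarnings(evaluate_model(m, ds$test, task = "binary"))
  expect_equal(ev_b$n, length(ds$test$records))
  ev_t <- suppressWarnings(evaluate_model(m, ds$test, task = "ternary"))
  dis <- sum(vapply(ds$test$records, `[[`, "", "binary_label") == "diseased")
  expect_equal(ev_t$n, dis)
  # bitwise reproducible
  ev_b2 <- suppressWarnings(evaluate_model(m, ds$test, task = "binary"))
  expect_identical(ev_b$metrics$accuracy, ev_b2$metrics$accuracy)
  expect_identical(ev_b$confusion$matrix, ev_b2$confusion$matrix)
  expect_error(evaluate_model(m, list(records = list()), task = "binary"),
               "empty")
})

test_that("an always-diseased predictor has recall 1 and accuracy = prevalence", {
  ds <- desk_dataset()
  m <- flater_model(micro_config(), seed = 1)
  # force the binary head to always say diseased
  m$params$head_bin$W[] <- 0
  m$params$head_bin$b <- c(-10, 10)
  ev <- evaluate_model(m, ds$test, task = "binary")
  ybin <- vapply(ds$test$records, `[[`, "", "binary_label")
  expect_equal(ev$metrics$recall, 1)
  expect_equal(ev$metrics$accuracy, mean(ybin == "diseased"))
})

test_that("progressive evaluation emits one consistent row per rate", {
  ds <- desk_dataset()
  m <- flater_model(micro_config(), seed = 2)
  merged <- c(ds$validation$records, ds$test$records)
  tab <- suppressWarnings(
    progressive_evaluation(m, merged, rates = c(0.5, 1), seed = 7,
                           task = "binary"))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$quantity, c(floor(0.5 * length(merged)), length(merged)))
  full <- suppressWarnings(evaluate_model(m, merged, task = "binary"))
  expect_equal(tab$accuracy[2], full$metrics$accuracy)
  tab2 <- suppressWarnings(
    progressive_evaluation(m, merged, rates = c(0.5, 1), seed = 7,
                           task = "binary"))
  expect_identical(tab, tab2)
})

test_that("saliency maps are unit-scaled and flat for constant input", {
  m <- flater_model(micro_config(), seed = 3)
  img <- rand_image(32, 32, seed = 12)
  s <- saliency_map(m, img)
  expect_equal(dim(s), c(32, 32))
  expect_gte(min(s), 0)
  expect_lte(max(s), 1)
  # constant input: flat away from the zero-padded convolution border (whose
  # influence reaches ~6 px here after the stem's downsample/upsample)
  flat <- saliency_map(m, array(0.2, c(32, 32, 3)))
  interior <- flat[7:26, 7:26]
  expect_equal(max(interior) - min(interior), 0, tolerance = 1e-12)
})
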