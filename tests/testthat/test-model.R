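test_that("forward pass emits well-formed head outputs", {
  m <- flater_model(micro_config(), seed = 1)
  xs <- lapply(1:3, function(i) rand_image(32, 32, seed = i))
  out <- model_forward(m, xs)
  expect_equal(dim(out$binary_logits), c(3L, 2L))
  expect_equal(dim(out$ternary_logits), c(3L, 3L))
  pb <- exp(out$binary_logits) / rowSums(exp(out$binary_logits))
  pt <- exp(out$ternary_logits) / rowSums(exp(out$ternary_logits))
  expect_equal(rowSums(pb), rep(1, 3), tolerance = 1e-6)
  expect_equal(rowSums(pt), rep(1, 3), tolerance = 1e-6)
  expect_error(model_forward(m, rand_image(16, 16, seed = 1)),
               "expected 32x32x3")
})

test_that("fixed seed gives bitwise-identical logits across runs", {
  build_and_run <- function() {
    m <- flater_model(micro_config(), seed = 7)
    model_forward(m, rand_image(32, 32, seed = 99))
  }
  a <- build_and_run()
  b <- build_and_run()
  expect_identical(a$binary_logits, b$binary_logits)
  expect_identical(a$ternary_logits, b$ternary_logits)
})

test_that("ablation variants map to the four studied architectures", {
  cfg <- micro_config()
  models <- lapply(c("full", "no_residual", "no_spatial_attention",
                     "vit_only"),
                   function(v) make_ablation_variant(cfg, v, seed = 1))
  names(models) <- c("full", "no_residual", "no_spatial_attention",
                     "vit_only")
  expect_null(models$no_residual$params$stem)
  expect_false(is.null(models$no_residual$params$sa))
  expect_null(models$no_spatial_attention$params$sa)
  expect_false(is.null(models$no_spatial_attention$params$stem))
  expect_null(models$vit_only$params$stem)
  expect_null(models$vit_only$params$sa)

  counts <- vapply(models, count_trainable_parameters, numeric(1))
  expect_lt(counts["vit_only"], counts["no_residual"])
  expect_lt(counts["no_residual"], counts["full"])
  expect_lt(counts["vit_only"], counts["no_spatial_attention"])
  expect_lt(counts["no_spatial_attention"], counts["full"])
  expect_identical(counts[["full"]],
                   count_trainable_parameters(flater_model(cfg, seed = 1)))
  expect_error(make_ablation_variant(cfg, "no_heads"), "valid variants")
})

test_that("parameter counts match the closed-form ledger at full width", {
  per_layer <- ledger_layer_params(768, 4)
  expect_equal(per_layer, 7087872)
  counts <- sapply(c(12, 6, 4), function(d) {
    count_trainable_parameters(flater_model(flater_config(depth = d),
                                            seed = 1))
  })
  expect_equal(counts[1] - counts[2], 6 * per_layer)
  expect_equal(counts[2] - counts[3], 2 * per_layer)
  expect_true(all(diff(counts) < 0))
  expect_equal(counts[1],
               ledger_total_params(flater_config(depth = 12), "full"))
})

test_that("parameter counts match the ledger for all variants and depths", {
  for (d in c(4, 2, 1)) {
    cfg <- flater_config(image_size = 32, patch_size = 16, embed_dim = 12,
                         stem_mid_channels = 4, num_heads = 2, depth = d,
                         mlp_ratio = 2)
    for (v in c("full", "no_residual", "no_spatial_attention", "vit_only")) {
      expect_equal(
        count_trainable_parameters(make_ablation_variant(cfg, v, seed = 1)),
        ledger_total_params(cfg, v),
        label = sprintf("depth %d variant %s", d, v))
    }
  }
})

test_that("a two-layer toy model's count matches a hand-summed ledger", {
  cfg <- flater_config(image_size = 8, patch_size = 4, embed_dim = 12,
                       stem_mid_channels = 2, num_heads = 2, depth = 2,
                       mlp_ratio = 2)
  m <- flater_model(cfg, seed = 1)
  hand <- sum(
    3 * 3 * 3 * 2 + 2,    # conv1 w + b
    2 + 2,                # bn1 gamma + beta
    3 * 3 * 2 * 3 + 3,    # conv2
    3 + 3,                # bn2
    1 * 1 * 3 * 3 + 3,    # conv3
    3 + 3,                # bn3
    48 * 12 + 12,         # patch projection (4*4*3 -> 12)
    12,                   # cls
    5 * 12,               # pos (4 patches + CLS)
    2 * (12 + 12 +        # per layer: ln1
         3 * (12 * 12 + 12) +  # q, k, v
         12 * 12 + 12 +   # output projection
         12 + 12 +        # ln2
         12 * 24 + 24 +   # mlp in
         24 * 12 + 12),   # mlp out
    12 + 12,              # final layer norm
    3 * 3 * 2 * 3 + 3,    # spatial-attention conv
    12 * 2 + 2,           # binary head
    12 * 3 + 3            # ternary head
  )
  expect_equal(count_trainable_parameters(m), hand)
})

test_that("checkpoints round-trip bitwise with a JSON sidecar", {
  m <- flater_model(micro_config(), seed = 11)
  x <- rand_image(32, 32, seed = 5)
  before <- model_forward(m, x)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path, history = data.frame(epoch = 1, loss = 0.5),
                  train_config = list(seed = 11))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$seed, 11)
  expect_equal(side$config$depth, 1)
  expect_true(length(side$parameters) > 10)
  restored <- load_checkpoint(path)
  after <- model_forward(restored$model, x)
  expect_identical(before$binary_logits, after$binary_logits)
  expect_identical(before$ternary_logits, after$ternary_logits)
  expect_equal(restored$train_config$seed, 11)
})

test_that("backbone weight loading overwrites the backbone and nothing else", {
  cfg <- micro_config()
  donor <- flater_model(cfg, seed = 1)
  arch <- tempfile(fileext = ".rds")
  save_checkpoint(donor, arch)
  target <- flater_model(cfg, seed = 2)
  stem_before <- target$params$stem
  res <- load_backbone_weights(target, arch)
  expect_identical(res$model$params$layers, donor$params$layers)
  expect_identical(res$model$params$patch, donor$params$patch)
  expect_identical(res$model$params$cls, donor$params$cls)
  expect_identical(res$model$params$stem, stem_before)
  expect_true(all(c("loaded", "skipped") %in% res$report$status))
  expect_true(all(grepl("^(head_|stem|sa)",
                        res$report$parameter[res$report$status == "skipped"])))
})

test_that("backbone loading truncates deeper archives only on request", {
  cfg2 <- flater_config(image_size = 32, patch_size = 16, embed_dim = 12,
                        stem_mid_channels = 4, num_heads = 2, depth = 2,
                        mlp_ratio = 2)
  donor <- flater_model(cfg2, seed = 1)
  arch <- tempfile(fileext = ".rds")
  save_checkpoint(donor, arch)
  shallow <- flater_model(micro_config(), seed = 3)  # depth 1
  expect_error(load_backbone_weights(shallow, arch), "truncate = TRUE")
  res <- load_backbone_weights(shallow, arch, truncate = TRUE)
  expect_identical(res$model$params$layers[[1]], donor$params$layers[[1]])
  # mismatched embed_dim names both dimensions
  wide <- flater_model(flater_config(image_size = 32, patch_size = 16,
                                     embed_dim = 27, num_heads = 3, depth = 1),
                       seed = 1)
  expect_error(load_backbone_weights(wide, arch), "12.*27|27.*12")
})
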