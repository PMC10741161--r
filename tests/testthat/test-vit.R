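test_that("patch counts follow the token-length law", {
  cfg <- flater_config()   # 224 / 16
  m <- flater_model(flater_config(image_size = 32, patch_size = 16,
                                  embed_dim = 12, num_heads = 2, depth = 1),
                    seed = 1)
  expect_equal(cfg$n_patches, 196L)
  expect_equal(cfg$n_tokens, 197L)
  expect_equal(cfg$patch_size^2 * cfg$in_channels, 768L)
  toks <- patch_embed(rand_image(32, 32, seed = 1), m)
  expect_equal(dim(toks), c(4L, 12L))
  withcls <- add_cls_and_positions(toks, m)
  expect_equal(nrow(withcls), nrow(toks) + 1L)
})

test_that("identity projection reproduces manually sliced patches", {
  # embed_dim = P^2 * C here (P = 2), so the projection can be the identity
  cfg <- flater_config(image_size = 4, patch_size = 2, embed_dim = 12,
                       num_heads = 2, depth = 1)
  m <- flater_model(cfg, seed = 1)
  m$params$patch$W <- diag(12)
  m$params$patch$b[] <- 0
  x <- rand_image(4, 4, seed = 8)
  toks <- patch_embed(x, m)
  # row-major grid order; row-major channel-last flattening
  manual <- function(gi, gj) {
    v <- numeric(12)
    k <- 0
    for (i in 1:2) for (j in 1:2) for (c in 1:3) {
      k <- k + 1
      v[k] <- x[(gi - 1) * 2 + i, (gj - 1) * 2 + j, c]
    }
    v
  }
  expect_equal(toks[1, ], manual(1, 1))
  expect_equal(toks[2, ], manual(1, 2))
  expect_equal(toks[3, ], manual(2, 1))
  expect_equal(toks[4, ], manual(2, 2))
})

test_that("patchify refuses non-divisible feature maps", {
  m <- flater_model(tiny_config(), seed = 1)
  expect_error(patch_embed(rand_image(6, 6, seed = 1), m), "not divisible")
})

test_that("CLS and position embeddings behave additively and deterministically", {
  m <- flater_model(micro_config(), seed = 1)
  toks <- matrix(rnorm(4 * 12), 4, 12)
  m0 <- m
  m0$params$cls[] <- 0
  m0$params$pos[] <- 0
  out0 <- add_cls_and_positions(toks, m0)
  expect_equal(out0[-1, ], toks, ignore_attr = TRUE)
  expect_equal(out0[1, ], rep(0, 12))
  expect_identical(add_cls_and_positions(toks, m),
                   add_cls_and_positions(toks, m))
  # loading a wrong-length table is an explicit error, no interpolation
  expect_error(add_cls_and_positions(matrix(0, 9, 12), m),
               "position-embedding")
})

test_that("encoder layer with zeroed output projections is the identity", {
  m <- flater_model(micro_config(), seed = 1)
  p <- m$params$layers[[1]]
  p$attn$Wo[] <- 0; p$attn$bo[] <- 0
  p$mlp$W2[] <- 0; p$mlp$b2[] <- 0
  m$params$layers[[1]] <- p
  x <- matrix(rnorm(5 * 12), 5, 12)
  expect_equal(encoder_layer(x, m), x, tolerance = 1e-12)
})

test_that("encoder layer matches the hand-rolled attention oracle", {
  # single head, 3 tokens, dim 4
  cfg <- flater_config(image_size = 4, patch_size = 2, embed_dim = 12,
                       num_heads = 1, depth = 1, mlp_ratio = 2)
  set.seed(21)
  p <- flater:::encoder_layer_init(
    flater_config(image_size = 2, patch_size = 2, embed_dim = 12,
                  num_heads = 1, depth = 1, mlp_ratio = 2))
  # shrink to dim 4 by hand to keep the oracle tiny
  D <- 4
  p4 <- list(ln1_gamma = runif(D, 0.5, 1.5), ln1_beta = rnorm(D),
             attn = list(Wq = matrix(rnorm(D * D), D), bq = rnorm(D),
                         Wk = matrix(rnorm(D * D), D), bk = rnorm(D),
                         Wv = matrix(rnorm(D * D), D), bv = rnorm(D),
                         Wo = matrix(rnorm(D * D), D), bo = rnorm(D)),
             ln2_gamma = runif(D, 0.5, 1.5), ln2_beta = rnorm(D),
             mlp = list(W1 = matrix(rnorm(D * 2 * D), D), b1 = rnorm(2 * D),
                        W2 = matrix(rnorm(2 * D * D), 2 * D), b2 = rnorm(D)))
  x <- matrix(rnorm(3 * D), 3, D)
  cfg1 <- list(num_heads = 1L, dropout = 0)
  got <- flater:::encoder_layer_fwd(x, p4, cfg1)$out
  expect_equal(got, naive_encoder_layer(x, p4, 1), tolerance = 1e-6)
})

test_that("encoder layers preserve shape at any depth", {
  for (depth in c(1, 3)) {
    cfg <- flater_config(image_size = 8, patch_size = 4, embed_dim = 12,
                         num_heads = 3, depth = depth)
    m <- flater_model(cfg, seed = 1)
    x <- matrix(rnorm(cfg$n_tokens * 12), cfg$n_tokens, 12)
    for (l in seq_len(depth)) x <- encoder_layer(x, m, layer = l)
    expect_equal(dim(x), c(cfg$n_tokens, 12L))
  }
})
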