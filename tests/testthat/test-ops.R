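# Oracle equivalence of the numerical primitives against direct-definition
# implementations on small inputs, plus finite-difference validation of the
# hand-written backward passes.

test_that("vectorised convolutions match the nested-loop oracle", {
  set.seed(10)
  for (case in list(list(h = 6, w = 6, cin = 3, cout = 4, stride = 1, pad = 1),
                    list(h = 8, w = 6, cin = 2, cout = 3, stride = 2, pad = 1),
                    list(h = 4, w = 4, cin = 3, cout = 2, stride = 1, pad = 0))) {
    x <- array(rnorm(case$h * case$w * case$cin), c(case$h, case$w, case$cin))
    w <- array(rnorm(9 * case$cin * case$cout), c(3, 3, case$cin, case$cout))
    b <- rnorm(case$cout)
    want <- naive_conv2d(x, w, b, stride = case$stride, pad = case$pad)

    got1 <- flater:::conv2d_fwd(x, w, b, stride = case$stride,
                                pad = case$pad)$out
    expect_equal(got1, want, tolerance = 1e-10)

    xb <- array(x, c(dim(x), 1))            # H x W x C x 1 -> H x W x 1 x C
    xb <- aperm(xb, c(1, 2, 4, 3))
    got2 <- flater:::conv2d_batch_fwd(xb, w, b, stride = case$stride,
                                      pad = case$pad)$out
    hout <- dim(want)[1]; wout <- dim(want)[2]
    expect_equal(array(got2, c(hout, wout, case$cout)), want,
                 tolerance = 1e-10)
  }
})

test_that("bilinear resize matches the direct interpolation oracle", {
  set.seed(11)
  x <- array(rnorm(4 * 6 * 3), c(4, 6, 3))
  expect_equal(flater:::resize_bilinear(x, 8, 12), naive_bilinear(x, 8, 12),
               tolerance = 1e-12)
  expect_equal(flater:::resize_bilinear(x, 3, 5), naive_bilinear(x, 3, 5),
               tolerance = 1e-12)
  # the dense-matrix path (used where backprop needs the exact transpose)
  Ru <- flater:::bilinear_matrix(4, 8)
  Cu <- flater:::bilinear_matrix(6, 12)
  for (c in 1:3) {
    expect_equal(Ru %*% x[, , c] %*% t(Cu),
                 naive_bilinear(x, 8, 12)[, , c], tolerance = 1e-12)
  }
})

test_that("network backward pass matches central finite differences", {
  cfg <- tiny_config()
  m <- flater_model(cfg, seed = 3)
  set.seed(7)
  B <- 2
  xb <- flater:::as_batch(lapply(1:B, function(i) rand_image(8, 8, seed = i)))
  ybin <- c("normal", "diseased")
  yter <- c(NA, "polyps")

  loss_of <- function(model) {
    ff <- flater:::model_forward_full(model, xb, training = TRUE)
    joint_loss(ff$out, ybin, yter)$total
  }
  ff <- flater:::model_forward_full(m, xb, training = TRUE)
  gl <- flater:::joint_loss_grads(ff$out, ybin, yter, 1, 1)
  g <- flater:::model_backward(m, ff$cache, gl$dbin, gl$dter)

  paths <- list(c("stem", "conv1_w"), c("stem", "bn2_gamma"),
                c("stem", "conv3_w"), c("patch", "W"), "cls", "pos",
                list("layers", 1L, "attn", "Wq"),
                list("layers", 2L, "mlp", "W1"),
                "ln_f_gamma", c("sa", "conv_w"),
                c("head_bin", "W"), c("head_ter", "b"))
  eps <- 1e-5
  set.seed(11)
  for (pth in paths) {
    pth <- as.list(pth)
    garr <- g
    arr <- m$params
    for (k in pth) { arr <- arr[[k]]; garr <- garr[[k]] }
    i <- sample(length(arr), 1)
    perturb <- function(delta) {
      m2 <- m
      node <- m2$params
      # rebuild nested list with one perturbed element
      setval <- function(tree, keys) {
        if (length(keys) == 0) {
          tree[i] <- tree[i] + delta
          return(tree)
        }
        tree[[keys[[1]]]] <- setval(tree[[keys[[1]]]], keys[-1])
        tree
      }
      m2$params <- setval(m2$params, pth)
      m2
    }
    num <- (loss_of(perturb(eps)) - loss_of(perturb(-eps))) / (2 * eps)
    expect_equal(garr[i], num, tolerance = 1e-3,
                 label = paste("grad", paste(unlist(pth), collapse = ".")))
  }
})

test_that("every parameter group receives gradient on a mixed batch", {
  m <- flater_model(tiny_config(), seed = 5)
  xb <- flater:::as_batch(lapply(1:4, function(i) rand_image(8, 8, seed = i)))
  ff <- flater:::model_forward_full(m, xb, training = TRUE)
  gl <- flater:::joint_loss_grads(ff$out,
                                  c("normal", "diseased", "diseased", "diseased"),
                                  c(NA, "ulcerative-colitis", "polyps",
                                    "esophagitis"), 1, 1)
  g <- flater:::model_backward(m, ff$cache, gl$dbin, gl$dter)
  leaves <- rapply(g, function(x) max(abs(x)), how = "unlist")
  expect_true(all(leaves > 0),
              info = paste("zero-gradient leaves:",
                           paste(names(leaves)[leaves == 0], collapse = ", ")))
})
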