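test_that("parameter counts match the published budget", {
  base <- build_model(model_config(num_classes = 1000), sk_cfg = NULL)
  expect_equal(base$param_report$total, 7978856)
  expect_equal(base$param_report$sk, 0)

  sk <- build_model(model_config(num_classes = 1000), sk_config())
  expect_equal(sk$param_report$base, 7978856)
  expect_equal(sk$param_report$sk, 322944)
  expect_equal(sk$param_report$total, 8301800)
})

test_that("dense blocks obey the channel arithmetic", {
  x <- array(rnorm(6 * 6 * 2 * 64), c(6, 6, 2, 64))
  y <- dense_block_forward(x, n_layers = 6, K = 32)
  expect_equal(dim(y), c(6, 6, 2, 256))
  x2 <- array(rnorm(4 * 4 * 2 * 128), c(4, 4, 2, 128))
  expect_equal(dim(dense_block_forward(x2, 12, 32))[4], 512)
  expect_identical(dense_block_forward(x, 0, 32), x)
})

test_that("SK branch outputs and the gated output keep the input shape", {
  set.seed(1)
  mod <- sk_module(16, sk_config(conv_groups = 4, dim_floor = 8), seed = 2)
  x <- array(rnorm(5 * 7 * 3 * 16), c(5, 7, 3, 16))
  br <- sk_split(mod, x)
  expect_equal(dim(br$Y1), dim(x))
  expect_equal(dim(br$Y2), dim(x))
  V <- sk_apply(mod, x)
  expect_equal(dim(V), dim(x))
})

test_that("the fuse descriptor dimension is max(C/r, floor)", {
  cfg <- sk_config(reduction_ratio = 16, dim_floor = 32)
  expect_equal(sk_fuse_dim(1024, cfg), 64L)
  expect_equal(sk_fuse_dim(128, cfg), 32L)
  expect_equal(sk_fuse_dim(32, cfg), 32L)
  # constant channel value pools to itself
  mod <- sk_module(4, sk_config(conv_groups = 1, dim_floor = 2), seed = 1)
  Y1 <- array(3, c(4, 4, 2, 4))
  Y2 <- array(-1, c(4, 4, 2, 4))
  fu <- sk_fuse(mod, Y1, Y2)
  expect_true(all(fu$s == 2))          # spatial mean of 3 + (-1)
})

test_that("SK gates always sum to one (100 random forwards)", {
  worst <- 0
  for (seed in 1:100) {
    set.seed(seed)
    C <- sample(c(8, 16, 32), 1)
    mod <- sk_module(C, sk_config(conv_groups = 4,
                                  dim_floor = sample(c(4, 8, 32), 1)),
                     seed = seed)
    x <- array(rnorm(4 * 4 * 2 * C), c(4, 4, 2, C))
    br <- sk_split(mod, x)
    fu <- sk_fuse(mod, br$Y1, br$Y2)
    sel <- sk_select(mod, fu$z, br$Y1, br$Y2)
    worst <- max(worst, max(abs(sel$a + sel$b - 1)))
  }
  expect_lt(worst, 1e-12)
})

test_that("symmetric selector weights average the branches", {
  mod <- sk_module(8, sk_config(conv_groups = 2, dim_floor = 4), seed = 3)
  mod$params$B <- mod$params$A
  x <- array(rnorm(4 * 4 * 2 * 8), c(4, 4, 2, 8))
  br <- sk_split(mod, x)
  fu <- sk_fuse(mod, br$Y1, br$Y2)
  sel <- sk_select(mod, fu$z, br$Y1, br$Y2)
  expect_true(all(abs(sel$a - 0.5) < 1e-12))
  expect_equal(sel$V, (br$Y1 + br$Y2) / 2)
  # degenerate gate: a -> 1 recovers the first branch
  mod$params$A <- mod$params$A + 50
  sel1 <- sk_select(mod, pmax(fu$z, 0.1), br$Y1, br$Y2)
  expect_true(all(sel1$a > 1 - 1e-6))
  expect_equal(sel1$V, br$Y1, tolerance = 1e-4)
})

test_that("focal loss reduces to cross-entropy and scales by (1-p)^gamma", {
  expect_equal(focal_loss(1, gamma = 2, alpha = 0.25), 0)
  p <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE)
  y <- c(1L, 2L)
  ce <- mean(-log(c(0.9, 0.7)))
  expect_equal(focal_loss(p, y, gamma = 0, alpha = 1), ce)
  expect_equal(focal_loss(0.9, gamma = 2, alpha = 0.25),
               -0.25 * 0.1^2 * log(0.9))
  expect_warning(focal_loss(c(1, 0), gamma = 2), "clamped")
})

test_that("the focal-loss gradient matches finite differences", {
  set.seed(4)
  logits <- matrix(rnorm(8), 4, 2)
  y <- c(1L, 2L, 2L, 1L)
  fg <- focal_loss_grad(logits, y, gamma = 2, alpha = 0.25)
  eps <- 1e-6
  for (i in c(1, 4)) for (j in 1:2) {
    lp <- logits; lp[i, j] <- lp[i, j] + eps
    lm <- logits; lm[i, j] <- lm[i, j] - eps
    num <- (focal_loss_grad(lp, y)$loss - focal_loss_grad(lm, y)$loss) /
      (2 * eps)
    expect_equal(fg$dlogits[i, j], num, tolerance = 1e-5)
  }
})

test_that("every parameter receives gradient on a random batch", {
  cfg <- model_config(growth_rate = 4, block_layout = c(2, 2),
                      num_classes = 2, input_size = 12, in_channels = 1,
                      bn_size = 2, stem_channels = 6, stem_kernel = 3,
                      stem_stride = 1, stem_pool = FALSE)
  mod <- build_model(cfg, sk_config(conv_groups = 2, dim_floor = 4),
                     seed = 5)
  set.seed(6)
  x <- array(rnorm(12 * 12 * 4), c(12, 12, 4, 1))
  y <- c(1L, 2L, 1L, 2L)
  fwd <- model_forward(mod, x, train = TRUE)
  expect_equal(ncol(fwd$logits), 2)
  fg <- focal_loss_grad(fwd$logits, y)
  g <- flatten_params(model_backward(mod, fwd$caches, fg$dlogits)$grads)
  p <- flatten_params(model_params(mod))
  expect_setequal(names(g), names(p))
  nonzero <- vapply(g, function(gi) any(gi != 0), logical(1))
  expect_true(all(nonzero))
})

test_that("the model overfits a 16-sample batch within 200 steps", {
  set.seed(7)
  cfg <- model_config(growth_rate = 4, block_layout = c(2, 2),
                      num_classes = 2, input_size = 16, in_channels = 1,
                      bn_size = 2, stem_channels = 6, stem_kernel = 3,
                      stem_stride = 1, stem_pool = FALSE)
  mod <- build_model(cfg, sk_config(conv_groups = 2, dim_floor = 4),
                     seed = 8)
  x <- array(rnorm(16 * 16 * 16), c(16, 16, 16, 1))
  y <- rep(c(1L, 2L), 8)
  # make the task learnable: shift class-2 images
  x[, , y == 2L, ] <- x[, , y == 2L, ] + 1
  fit <- train_model(mod, x, y,
                     train_config(epochs = 200, batch_size = 16, seed = 9))
  expect_lt(min(fit$history$loss), 0.01)
})
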