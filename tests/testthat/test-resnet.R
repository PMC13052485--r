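# Closed-form parameter count, independent of the implementation: walks the
# layer plan (conv weights without bias, batch-norm affine pairs, strided
# 1x1 projection per block, linear head) and sums sizes.
closed_form_params <- function(cfg) {
  k <- cfg$kernel_size
  total <- cfg$initial_filters * 1 * k + 2 * cfg$initial_filters
  c_prev <- cfg$initial_filters
  for (b in seq_len(cfg$n_blocks)) {
    cb <- cfg$block_channels[b]
    for (j in seq_len(cfg$convs_per_block)) {
      cin <- if (j == 1) c_prev else cb
      total <- total + cb * cin * k + 2 * cb
    }
    total <- total + cb * c_prev * 1 + 2 * cb
    c_prev <- cb
  }
  l <- cfg$input_length
  for (i in seq_len(cfg$n_blocks + 1)) l <- ceiling(l / cfg$downsample_stride)
  total + cfg$n_classes * c_prev * l + cfg$n_classes
}

test_that("builds are seed-deterministic and feature lengths follow iterated ceil(L/2)", {
  cfg <- tiny_net()
  m1 <- build_resnet1d(cfg, seed = 3)
  m2 <- build_resnet1d(cfg, seed = 3)
  expect_identical(m1$params, m2$params)
  m3 <- build_resnet1d(cfg, seed = 4)
  expect_false(identical(m1$params, m3$params))

  lens <- ramanadapt:::feature_lengths(model_config())
  expect_equal(lens, c(587, 294, 147, 74, 37, 19, 10))

  expect_error(model_config(input_length = 64), "minimum")
  expect_error(model_config(kernel_size = 4), "odd")
})

test_that("default configuration hits the published parameter budget and the closed-form sum", {
  m <- build_resnet1d(model_config(), seed = 1)
  n <- count_parameters(m)
  expect_equal(n, closed_form_params(model_config()))
  expect_lt(abs(n - 1.25e6) / 1.25e6, 0.04)
})

test_that("parameter counts match the closed form for random configurations", {
  set.seed(11)
  for (i in 1:3) {
    cfg <- model_config(input_length = sample(200:800, 1),
                        initial_filters = sample(4:20, 1),
                        block_channels = sample(4:20, 6, replace = TRUE))
    m <- build_resnet1d(cfg, seed = i)
    expect_equal(count_parameters(m), closed_form_params(cfg))
    # shape trace: activations really have the predicted lengths
    fw <- ramanadapt:::resnet_forward(m, matrix(rnorm(2 * cfg$input_length), 2),
                                      want_cache = TRUE)
    expect_equal(fw$caches[["head.in_dim"]],
                 c(utils::tail(cfg$block_channels, 1),
                   utils::tail(ramanadapt:::feature_lengths(cfg), 1), 2))
  }
})

test_that("the head group alone has channels x length x classes + classes parameters", {
  cfg <- model_config(input_length = 1174, initial_filters = 100,
                      block_channels = rep(100L, 6))
  m <- build_resnet1d(cfg, seed = 1)
  expect_equal(count_parameters(m, trainable_only = TRUE,
                                trainable_groups = "head"),
               100 * 10 * 2 + 2)
  expect_error(count_parameters(m, trainable_only = TRUE,
                                trainable_groups = "block_9"),
               "unknown group")
})

test_that("predict_proba returns valid, deterministic class distributions", {
  m <- build_resnet1d(tiny_net(), seed = 5)
  x <- matrix(rnorm(4 * 256), 4)
  p <- predict_proba(m, x)
  expect_equal(rowSums(p), rep(1, 4))
  expect_true(all(p >= 0 & p <= 1))
  p0 <- predict_proba(m, matrix(0, 1, 256))
  expect_equal(sum(p0), 1)
  dup <- predict_proba(m, x[c(1, 1), ])
  expect_equal(dup[1, ], dup[2, ])
  expect_error(predict_proba(m, matrix(0, 1, 100)), "expected 256")
})

test_that("randomly initialized models are not grossly biased toward one class", {
  probs <- vapply(1:10, function(s) {
    m <- build_resnet1d(tiny_net(), seed = s)
    x <- matrix(rnorm(20 * 256), 20)
    mean(predict_proba(m, x)[, 2])
  }, 1)
  expect_gt(mean(probs), 0.2)
  expect_lt(mean(probs), 0.8)
})

test_that("compiled convolution kernels agree with the plain-R reference", {
  set.seed(99)
  for (i in 1:5) {
    C <- sample(1:6, 1); L <- sample(20:60, 1); N <- sample(1:4, 1)
    k <- sample(c(1, 3, 5), 1); s <- sample(1:2, 1); Co <- sample(1:7, 1)
    pad <- (k - 1) %/% 2
    x <- array(rnorm(C * L * N), c(C, L, N))
    W <- matrix(rnorm(Co * C * k), Co)
    a <- ramanadapt:::conv1d_forward(x, W, s, pad)
    b <- ramanadapt:::conv1d_forward_ref(x, W, s, pad)
    expect_equal(as.numeric(a$y), as.numeric(b$y))
    dy <- array(rnorm(length(a$y)), dim(a$y))
    ga <- ramanadapt:::conv1d_backward(dy, a$cols, W, dim(x), s, pad)
    gb <- ramanadapt:::conv1d_backward_ref(dy, b$cols, W, dim(x), s, pad)
    expect_equal(ga$dW, gb$dW)
    expect_equal(as.numeric(ga$dx), as.numeric(gb$dx))
  }
})

test_that("analytic gradients match finite differences through the whole network", {
  cfg <- model_config(input_length = 160, initial_filters = 5,
                      block_channels = rep(5L, 6))
  m <- build_resnet1d(cfg, seed = 2)
  x <- matrix(rnorm(4 * 160), 4); y <- c(0, 1, 1, 0)
  fw <- ramanadapt:::resnet_forward(m, x, mode = "train", want_cache = TRUE)
  lg <- ramanadapt:::ce_loss_grad(fw$logits, y)
  gr <- ramanadapt:::resnet_backward(m, fw$caches, lg$dlogits, "train")
  loss_at <- function(mm) {
    f <- ramanadapt:::resnet_forward(mm, x, mode = "train")
    ramanadapt:::ce_loss_grad(f$logits, y)$loss
  }
  set.seed(9)
  for (nm in c("stem.conv.W", "block_2.conv_3.W", "block_4.bn_1.gamma",
               "block_6.short.W", "head.W")) {
    i <- sample(length(m$params[[nm]]), 1)
    eps <- 1e-5
    mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    mn <- m; mn$params[[nm]][i] <- mn$params[[nm]][i] - eps
    fd <- (loss_at(mp) - loss_at(mn)) / (2 * eps)
    expect_equal(gr[[nm]][i], fd, tolerance = 1e-4)
  }
})

test_that("checkpoints round-trip bit-identically and reject mismatched configs", {
  m <- build_resnet1d(tiny_net(), seed = 8)
  x <- matrix(rnorm(3 * 256), 3)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(predict_proba(m, x), predict_proba(m2, x))
  expect_identical(m2$groups, m$groups)  # group name map preserved
  expect_error(load_checkpoint(path, config = tiny_net(input_length = 128)),
               "input_length")
  expect_silent(load_checkpoint(path, config = tiny_net()))
})
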