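test_that("mixed pooling interpolates between max and average pooling", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)  # columns: (1,3), (2,4)
  expect_equal(mixed_pool(m, lambda = 1), 4)
  expect_equal(mixed_pool(m, lambda = 0), 2.5)
  expect_equal(mixed_pool(matrix(7, 4, 4), lambda = 0.37),
               matrix(7, 2, 2))
  set.seed(5)
  for (i in 1:6) {
    nr <- sample(4:8, 1) * 2
    mm <- matrix(rnorm(nr * 4), nr, 4)
    lam <- runif(1)
    expect_equal(mixed_pool(mm, lam), oracle_mixed_pool(mm, lam),
                 tolerance = 1e-12)
  }
})

test_that("coordinate attention preserves shape and never amplifies", {
  set.seed(6)
  x <- array(rnorm(6 * 5 * 8 * 2), c(6, 5, 8, 2))
  y <- coordinate_attention(x, reduction = 4)
  expect_identical(dim(y), dim(x))
  expect_true(all(abs(y) <= abs(x)))
  # constant input: axis-pooled activations are all that constant
  xc <- array(3.5, c(4, 4, 8))
  yc <- coordinate_attention(xc, reduction = 2)
  expect_true(all(abs(attr(yc, "Mh") - 3.5) < 1e-12))
  expect_true(all(abs(attr(yc, "Mw") - 3.5) < 1e-12))
  expect_error(coordinate_attention(x, reduction = 16), "reduction")
})

test_that("depthwise-separable convolution composes its two stages", {
  expect_identical(64L * 9L + 64L * 128L, 8768L)  # vs 73,728 standard
  # 1x1 depthwise kernel of ones + identity pointwise = identity map
  set.seed(8)
  x <- array(rnorm(5 * 5 * 3 * 2), c(5, 5, 3, 2))
  Wd1 <- array(1, c(1, 1, 3))
  expect_equal(depthwise_separable_conv(x, Wd1, diag(3)), x)
  # matches the naive two-stage oracle
  Wd <- array(rnorm(3 * 3 * 3), c(3, 3, 3))
  Wp <- matrix(rnorm(3 * 4), 3, 4)
  b <- rnorm(4)
  got <- depthwise_separable_conv(x, Wd, Wp, b)
  for (s in 1:2) {
    expect_equal(got[, , , s], oracle_dwsep(x[, , , s], Wd, Wp, b),
                 tolerance = 1e-9)
  }
  expect_error(depthwise_separable_conv(x, array(1, c(2, 2, 3)), Wp),
               "odd")
})

test_that("binary cross-entropy matches its closed forms", {
  expect_lt(bce_loss(1, 1 - 1e-15), 1e-12)
  expect_equal(bce_loss(0, 0.5), log(2), tolerance = 1e-12)
  for (p in c(0.1, 0.33, 0.9)) {
    expect_equal(bce_loss(1, p), bce_loss(0, 1 - p), tolerance = 1e-12)
  }
  expect_equal(bce_loss(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_true(is.finite(bce_loss(1, 0)))  # clipping
})

test_that("all group counts in 1..5 build and emit a probability", {
  set.seed(1)
  x <- array(rnorm(32 * 32), c(32, 32, 1, 1))
  for (ng in 1:5) {
    cfg <- lcacnn_config(n_groups = ng, channels = c(8, 8, 16, 16, 16),
                         ca_reduction = 4, seed = 2)
    model <- build_model(cfg)
    p <- predict(model, x)
    expect_length(p, 1)
    expect_gt(p, 0); expect_lt(p, 1)
  }
  expect_identical(lcacnn_config()$n_groups, 4L)
  expect_error(lcacnn_config(n_groups = 6), "1..5")
  # spatial collapse is reported with the offending group
  tiny <- lcacnn_config(n_groups = 3, channels = c(4, 4, 4),
                        ca_reduction = 2, input_shape = c(4, 4))
  expect_error(build_model(tiny), "group 3")
})

test_that("forward passes are deterministic given weights and lambda", {
  cfg <- lcacnn_config(n_groups = 2, channels = c(4, 8), ca_reduction = 2,
                       input_shape = c(8, 8), seed = 11)
  model <- build_model(cfg)
  set.seed(3)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 1, 3))
  expect_identical(predict(model, x), predict(model, x))
})

test_that("backpropagation matches finite differences", {
  cfg <- lcacnn_config(n_groups = 3, channels = c(4, 4, 8),
                       ca_reduction = 2, input_shape = c(8, 8), seed = 5)
  model <- build_model(cfg)
  set.seed(9)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 1, 3))
  y <- c(0, 1, 1)
  lam <- c(1, 0, 0.5)
  loss_fn <- function(m) {
    bce_loss(y, phonoscreen:::lcacnn_forward(m, x, lambdas = lam,
                                             training = TRUE)$p)
  }
  fw <- phonoscreen:::lcacnn_forward(model, x, lambdas = lam,
                                     training = TRUE, keep_cache = TRUE)
  gr <- phonoscreen:::grads_as_parameters(
    phonoscreen:::lcacnn_backward(model, fw,
                                  matrix((fw$p - y) / 3, ncol = 1)),
    model)
  eps <- 1e-6
  for (spec in list(c("g1", "conv", "W"), c("g2", "ca", "W1"),
                    c("g2", "bn", "gamma"), c("g3", "conv", "Wd"),
                    c("g3", "conv", "Wp"), c("g3", "ca", "Ww"))) {
    g <- gr[[spec[1]]][[spec[2]]][[spec[3]]]
    i <- which.max(abs(g))
    pp <- phonoscreen:::model_parameters(model)
    v <- pp[[spec[1]]][[spec[2]]][[spec[3]]]
    v[i] <- v[i] + eps
    pp[[spec[1]]][[spec[2]]][[spec[3]]] <- v
    l1 <- loss_fn(phonoscreen:::set_model_parameters(model, pp))
    v[i] <- v[i] - 2 * eps
    pp[[spec[1]]][[spec[2]]][[spec[3]]] <- v
    l0 <- loss_fn(phonoscreen:::set_model_parameters(model, pp))
    num <- (l1 - l0) / (2 * eps)
    expect_lt(abs(g[i] - num) / max(abs(num), 1e-8), 1e-3,
              label = paste(spec, collapse = "$"))
  }
})

test_that("separable groups cut the parameter count", {
  cfg_sep <- lcacnn_config(seed = 1)
  cfg_std <- lcacnn_config(standard_groups = 4L, seed = 1)
  expect_lt(count_parameters(build_model(cfg_sep)),
            count_parameters(build_model(cfg_std)))
})

test_that("training reduces the loss and can overfit a tiny set", {
  set.seed(77)
  n <- 16
  x <- array(rnorm(16 * 16 * n), c(16, 16, 1, n))
  y <- rep(c(0, 1), each = n / 2)
  # separable signal: class 1 has an energetic band
  x[5:8, , 1, y == 1] <- x[5:8, , 1, y == 1] + 2
  cfg <- lcacnn_config(n_groups = 2, channels = c(8, 16),
                       ca_reduction = 4, input_shape = c(16, 16),
                       batch_size = 8, epochs = 20, seed = 21)
  model <- train_lcacnn(x, y, cfg)
  hist <- attr(model, "history")
  expect_lt(hist$loss[5], hist$loss[1])
  expect_identical(hist$accuracy[nrow(hist)], 1)
  p <- predict(model, x)
  expect_true(all((p >= 0.5) == (y == 1)))
  expect_error(train_lcacnn(x, rep(1, n), cfg), "both classes")
})

test_that("training is reproducible from the seed", {
  set.seed(55)
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 1, 8))
  y <- rep(c(0, 1), 4)
  cfg <- lcacnn_config(n_groups = 1, channels = 4, ca_reduction = 2,
                       input_shape = c(8, 8), batch_size = 4,
                       epochs = 3, seed = 13)
  m1 <- train_lcacnn(x, y, cfg)
  m2 <- train_lcacnn(x, y, cfg)
  expect_identical(phonoscreen:::model_parameters(m1),
                   phonoscreen:::model_parameters(m2))
})

test_that("models round-trip through JSON exactly", {
  cfg <- lcacnn_config(n_groups = 2, channels = c(4, 8), ca_reduction = 2,
                       input_shape = c(8, 8), seed = 17)
  model <- build_model(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_lcacnn(model, path)
  back <- read_lcacnn(path)
  set.seed(2)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  expect_identical(predict(back, x), predict(model, x))
})
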