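test_that("forward pass applies tanh hidden layers and a ReLU output", {
  # all-zero parameters: ReLU(0) = 0 whatever the input
  zero <- withr::with_seed(1L, nn_init(c(2L, 4L, 3L, 1L)))
  zero$weights <- lapply(zero$weights, function(w) w * 0)
  zero$biases <- lapply(zero$biases, function(b) b * 0)
  expect_equal(nn_forward(zero, matrix(runif(10), 5, 2)), rep(0, 5))

  # 1-1-1-1 chain with unit weights, zero biases: ReLU(tanh(tanh(1)))
  chain <- structure(list(layer_sizes = c(1L, 1L, 1L, 1L),
                          weights = list(matrix(1), matrix(1), matrix(1)),
                          biases = list(0, 0, 0)),
                     class = "network_params")
  expect_equal(nn_forward(chain, 1), 0.642014992012, tolerance = 1e-10)
  # a negative output pre-activation is clamped to zero
  chain$biases[[3]] <- -2
  expect_equal(nn_forward(chain, 1), 0)
  expect_error(nn_forward(chain, matrix(1, 1, 2)), "dimension mismatch")
})

test_that("MSE loss matches its definition and scales quadratically", {
  expect_equal(mse_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse_loss(c(0, 1), c(1, 0)), 1)
  y <- c(0.1, 0.4, 0.9); yhat <- c(0.2, 0.3, 0.7)
  expect_equal(mse_loss(y, y + 3 * (yhat - y)), 9 * mse_loss(y, yhat))
  expect_error(mse_loss(numeric(0), numeric(0)), "empty")
  expect_error(mse_loss(1:3, 1:2), "length")
})

test_that("analytic gradients match central finite differences", {
  for (seed in 1:3) {
    arch <- list(c(2L, 3L, 1L), c(1L, 3L, 2L, 1L), c(3L, 2L, 3L, 1L))[[seed]]
    params <- withr::with_seed(seed, nn_init(arch))
    x <- withr::with_seed(seed + 10L, matrix(runif(6L * arch[1L]), 6L, arch[1L]))
    y <- withr::with_seed(seed + 20L, runif(6L))
    got <- nn_gradients(params, x, y)
    want <- numeric_gradients(params, x, y)
    for (l in seq_along(got$weights)) {
      expect_equal(got$weights[[l]], want$weights[[l]], tolerance = 1e-5)
      expect_equal(got$biases[[l]], want$biases[[l]], tolerance = 1e-5)
    }
  }
})

test_that("gradients vanish on zero residuals and in the dead ReLU region", {
  params <- withr::with_seed(4L, nn_init(c(2L, 3L, 1L)))
  x <- matrix(runif(10), 5L, 2L)
  g <- nn_gradients(params, x, nn_forward(params, x))  # residuals all zero
  expect_true(all(vapply(g$weights, function(w) all(w == 0), TRUE)))
  # force every output pre-activation negative: output-layer gradients are 0
  params$biases[[2]] <- -10
  g2 <- nn_gradients(params, x, runif(5))
  expect_true(all(g2$weights[[2]] == 0))
  expect_true(all(g2$biases[[2]] == 0))
})

test_that("training learns a noiseless linear map", {
  x <- matrix(seq(0, 1, length.out = 50), ncol = 1)
  y <- 0.5 * x[, 1]
  fit <- nn_train(x, y, x, y, reference_net_layers(),
                  train_config(learning_rate = 0.01, max_epochs = 3000L,
                               seed = 1L))
  expect_lt(fit$history$train_mse[nrow(fit$history)], 1e-3)
  expect_true(fit$stop_reason %in% c("epoch_cap", "divergence", "threshold"))
})

test_that("training MSE is non-increasing at a small step size", {
  x <- matrix(seq(0, 1, length.out = 40), ncol = 1)
  y <- 0.5 * x[, 1]
  fit <- nn_train(x, y, x, y, c(1L, 4L, 1L),
                  train_config(learning_rate = 1e-3, max_epochs = 400L,
                               seed = 2L))
  expect_true(all(diff(fit$history$train_mse) <= 1e-12))
})

test_that("a zero learning rate leaves the parameters untouched", {
  x <- matrix(runif(20), 10L, 2L)
  y <- runif(10)
  init <- withr::with_seed(5L, enzisfet:::init_alive(c(2L, 3L, 1L), x, 1))
  fit <- nn_train(x, y, x, y, c(2L, 3L, 1L),
                  train_config(learning_rate = 0, max_epochs = 20L, seed = 5L))
  expect_equal(fit$params$weights, init$weights)
  expect_equal(fit$params$biases, init$biases)
})

test_that("training is deterministic given the seed and flags divergence", {
  d <- awgn_augment(generate_dataset(params = sim_params(seed = 1L),
                                     replicates = 2L), 5L, seed = 2L)
  sp <- split_dataset(d, 0.8, TRUE, seed = 3L)
  cfg <- train_config(max_epochs = 60L, seed = 9L)
  m1 <- train_concentration_model(sp$train, sp$test, cfg)
  m2 <- train_concentration_model(sp$train, sp$test, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$network$weights, m2$network$weights)
})

test_that("a non-finite loss aborts training with advice", {
  x <- matrix(runif(20), 10L, 2L)
  y <- c(runif(9), Inf)
  expect_error(
    nn_train(x, y, x, y, c(2L, 3L, 1L),
             train_config(max_epochs = 50L, seed = 1L)),
    "learning_rate")
  # an absurd step size must not silently leave non-finite parameters:
  # the ReLU dead region contains the blow-up instead
  fit <- nn_train(x, runif(10), x, runif(10), c(2L, 3L, 1L),
                  train_config(learning_rate = 1e5, max_epochs = 200L,
                               seed = 2L))
  expect_true(all(is.finite(unlist(fit$params$weights))))
})

test_that("the stated architectures are the presets", {
  expect_equal(concentration_net_layers(), c(2L, 20L, 16L, 1L))
  expect_equal(reference_net_layers(), c(1L, 10L, 5L, 1L))
})

test_that("a saved model file reproduces predictions bit-identically", {
  d <- awgn_augment(generate_dataset(params = sim_params(seed = 8L),
                                     replicates = 2L), 5L, seed = 8L)
  sp <- split_dataset(d, 0.8, TRUE, seed = 8L)
  m <- train_concentration_model(sp$train, sp$test,
                                 train_config(max_epochs = 30L, seed = 8L))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  x <- cbind(delta_vgs_mv = c(20, 30, 40), temperature_c = c(21, 27, 33))
  expect_identical(predict(m, x), predict(m2, x))
  expect_identical(m$network$weights, m2$network$weights)
  expect_equal(m$norm_x$min, m2$norm_x$min)
})
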