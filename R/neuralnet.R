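#' Training configuration for the gradient-descent networks
#'
#' @param learning_rate step size of full-batch gradient descent; the
#'   published protocol uses 0.01 for both networks.
#' @param max_epochs epoch cap: 5000 for the two-input concentration
#'   network, 3000 for the single-input reference network.
#' @param patience number of consecutive epochs of rising test MSE
#'   tolerated before training is declared divergent and stopped. The
#'   divergence rule is stated without a window in the protocol; 20 epochs
#'   is this package's operationalization.
#' @param mse_stop_threshold optional: stop once the training MSE (on the
#'   normalized scale) falls to or below this value. The reference network
#'   uses 0.01.
#' @param init_scale multiplier on the uniform(-0.5, 0.5) initialization.
#' @param seed integer seed for the (re-drawn, see [nn_train()]) random
#'   initialization.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, max_epochs = 5000L,
                         patience = 20L, mse_stop_threshold = NULL,
                         init_scale = 1, seed = 1L) {
  stopifnot(learning_rate >= 0, max_epochs >= 1L, patience >= 1L,
            is.null(mse_stop_threshold) || mse_stop_threshold > 0,
            init_scale > 0)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 mse_stop_threshold = mse_stop_threshold,
                 init_scale = init_scale, seed = as.integer(seed)),
            class = "train_config")
}

#' Layer presets for the two published architectures
#'
#' The two-input concentration model uses hidden layers of 20 and 16
#' nodes; the single-input reference model halves them to 10 and 5. Both
#' end in a single ReLU output node.
#'
#' @return Integer vector of layer sizes (inputs, hidden..., output).
#' @export
concentration_net_layers <- function() c(2L, 20L, 16L, 1L)

#' @rdname concentration_net_layers
#' @export
reference_net_layers <- function() c(1L, 10L, 5L, 1L)

#' Randomly initialize network parameters
#'
#' Weights and biases are drawn i.i.d. uniform(-0.5, 0.5) scaled by
#' `init_scale`, from the current RNG state.
#'
#' @param layer_sizes integer vector (inputs, hidden..., output).
#' @param init_scale multiplier on the draw.
#' @return An object of class `network_params`: `layer_sizes`, a list of
#'   weight matrices `weights` (one per layer transition, dims in x out),
#'   and a list of bias vectors `biases`.
#' @export
nn_init <- function(layer_sizes, init_scale = 1) {
  stopifnot(length(layer_sizes) >= 2L, all(layer_sizes >= 1L))
  L <- length(layer_sizes) - 1L
  w <- lapply(seq_len(L), function(l)
    matrix(init_scale * runif(layer_sizes[l] * layer_sizes[l + 1L], -0.5, 0.5),
           layer_sizes[l], layer_sizes[l + 1L]))
  b <- lapply(seq_len(L), function(l)
    init_scale * runif(layer_sizes[l + 1L], -0.5, 0.5))
  structure(list(layer_sizes = as.integer(layer_sizes), weights = w, biases = b),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat("feed-forward network", paste(x$layer_sizes, collapse = "-"),
      "(tanh hidden, ReLU output),",
      sum(vapply(x$weights, length, 0L)) + sum(vapply(x$biases, length, 0L)),
      "parameters\n")
  invisible(x)
}

## full forward pass keeping every activation, for backprop;
## A[[l]] is the input to layer l, Z[[l]] its pre-activation
forward_pass <- function(params, x) {
  L <- length(params$weights)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  A[[1L]] <- x
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% params$weights[[l]], 2L, params$biases[[l]], "+")
    A[[l + 1L]] <- if (l < L) tanh(Z[[l]]) else pmax(Z[[l]], 0)
  }
  list(A = A, Z = Z)
}

as_feature_matrix <- function(x, d) {
  if (is.null(dim(x))) {
    if (d == 1L) x <- matrix(x, ncol = 1L)
    else if (length(x) == d) x <- matrix(x, nrow = 1L)
    else stop("feature dimension mismatch: expected ", d, " columns", call. = FALSE)
  }
  x <- as.matrix(x)
  if (ncol(x) != d)
    stop("feature dimension mismatch: expected ", d, " columns, got ",
         ncol(x), call. = FALSE)
  ## drop names so parameter updates built from crossprod() stay unnamed
  dimnames(x) <- NULL
  attributes(x)$norm_params <- NULL
  x
}

#' Forward evaluation of a network
#'
#' Hidden layers apply tanh to affine combinations of their inputs; the
#' output layer applies ReLU, so predictions are non-negative -- matched to
#' targets normalized into \[0, 1\].
#'
#' @param params a `network_params` object.
#' @param x feature matrix (rows = observations) or vector.
#' @return Numeric vector of predictions (single output node), or a matrix
#'   for multi-output networks.
#' @export
nn_forward <- function(params, x) {
  stopifnot(inherits(params, "network_params"))
  x <- as_feature_matrix(x, params$layer_sizes[1L])
  out <- forward_pass(params, x)$A[[length(params$weights) + 1L]]
  if (ncol(out) == 1L) out[, 1L] else out
}

#' Mean squared error
#'
#' @param y observed values.
#' @param yhat predicted values, same length.
#' @return mean((y - yhat)^2).
#' @export
mse_loss <- function(y, yhat) {
  if (length(y) == 0L) stop("empty input", call. = FALSE)
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  mean((y - yhat)^2)
}

#' Analytic gradients of the MSE loss
#'
#' Exact backpropagation of the mean-squared-error loss through the tanh
#' hidden layers (derivative 1 - tanh^2) and the ReLU output (subgradient
#' 0 at exactly 0). Verified in the test suite against central finite
#' differences.
#'
#' @inheritParams nn_forward
#' @param y target vector.
#' @return List with `weights` and `biases` gradients, shaped like the
#'   parameters.
#' @export
nn_gradients <- function(params, x, y) {
  stopifnot(inherits(params, "network_params"))
  x <- as_feature_matrix(x, params$layer_sizes[1L])
  n <- nrow(x)
  stopifnot(length(y) == n)
  L <- length(params$weights)
  fp <- forward_pass(params, x)
  res <- fp$A[[L + 1L]][, 1L] - y
  ## dMSE/dZ_L: 2/n * residual through the ReLU (active where Z > 0)
  delta <- matrix(2 * res / n, n, 1L) * (fp$Z[[L]] > 0)
  gw <- vector("list", L)
  gb <- vector("list", L)
  for (l in L:1L) {
    gw[[l]] <- crossprod(fp$A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L)
      delta <- (delta %*% t(params$weights[[l]])) * (1 - fp$A[[l]]^2)
  }
  list(weights = gw, biases = gb)
}

## at initialization the single ReLU output can be inactive on every row,
## in which case no gradient ever reaches the network and training returns
## the constant 0 predictor; re-draw until a usable fraction of rows is
## active (deterministic given the RNG state)
init_alive <- function(layer_sizes, x, init_scale, min_alive = 0.05,
                       max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    params <- nn_init(layer_sizes, init_scale)
    fp <- forward_pass(params, x)
    if (mean(fp$Z[[length(params$weights)]] > 0) >= min_alive) return(params)
  }
  stop("could not find an initialization with an active output unit; ",
       "check feature scaling", call. = FALSE)
}

#' Train a network by full-batch gradient descent
#'
#' Plain (unaccelerated, full-batch) gradient descent on the MSE loss from
#' a seeded random initialization. Training stops at the epoch cap, when
#' the training MSE reaches `mse_stop_threshold` (if set), or when the
#' test MSE has risen for `patience` consecutive epochs (the divergence
#' rule). The parameters with the lowest recorded test MSE are returned,
#' not the last-epoch parameters.
#'
#' Inputs are expected min-max normalized into \[0, 1\] (features and
#' targets); see [minmax_normalize()].
#'
#' @param x_train,y_train normalized training features/targets.
#' @param x_test,y_test normalized held-out features/targets, used for the
#'   divergence rule and for selecting the returned parameters.
#' @param layer_sizes network architecture, e.g.
#'   [concentration_net_layers()].
#' @param config a [train_config()].
#' @return An object of class `trained_network`: `params`
#'   (`network_params` at the best test MSE), `history` (data frame of
#'   per-epoch `train_mse` / `test_mse`), `stop_reason` (`"epoch_cap"`,
#'   `"threshold"` or `"divergence"`), `best_epoch`.
#' @export
nn_train <- function(x_train, y_train, x_test, y_test,
                     layer_sizes = concentration_net_layers(),
                     config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  x_train <- as_feature_matrix(x_train, layer_sizes[1L])
  x_test <- as_feature_matrix(x_test, layer_sizes[1L])
  stopifnot(nrow(x_train) == length(y_train), nrow(x_test) == length(y_test))
  params <- withr::with_seed(config$seed,
    init_alive(layer_sizes, x_train, config$init_scale))
  L <- length(params$weights)
  n <- nrow(x_train)
  lr <- config$learning_rate
  train_mse <- numeric(config$max_epochs)
  test_mse <- numeric(config$max_epochs)
  best <- Inf; best_params <- params; best_epoch <- 0L
  rising <- 0L
  stop_reason <- "epoch_cap"
  epochs_run <- config$max_epochs
  for (e in seq_len(config$max_epochs)) {
    fp <- forward_pass(params, x_train)
    yhat <- pmax(fp$Z[[L]][, 1L], 0)
    res <- yhat - y_train
    train_mse[e] <- mean(res^2)
    if (!is.finite(train_mse[e]))
      stop("training loss became non-finite at epoch ", e,
           "; try a smaller learning_rate", call. = FALSE)
    test_mse[e] <- mse_loss(y_test, nn_forward(params, x_test))
    if (test_mse[e] < best) {
      best <- test_mse[e]; best_params <- params; best_epoch <- e
    }
    if (e > 1L) rising <- if (test_mse[e] > test_mse[e - 1L]) rising + 1L else 0L
    if (!is.null(config$mse_stop_threshold) &&
        train_mse[e] <= config$mse_stop_threshold) {
      stop_reason <- "threshold"; epochs_run <- e; break
    }
    if (rising >= config$patience) {
      stop_reason <- "divergence"; epochs_run <- e; break
    }
    ## backprop + descent step
    delta <- matrix(2 * res / n, n, 1L) * (fp$Z[[L]] > 0)
    for (l in L:1L) {
      gw <- crossprod(fp$A[[l]], delta)
      gb <- colSums(delta)
      if (l > 1L)
        delta <- (delta %*% t(params$weights[[l]])) * (1 - fp$A[[l]]^2)
      params$weights[[l]] <- params$weights[[l]] - lr * gw
      params$biases[[l]] <- params$biases[[l]] - lr * gb
    }
  }
  structure(list(params = best_params,
                 history = data.frame(epoch = seq_len(epochs_run),
                                      train_mse = train_mse[seq_len(epochs_run)],
                                      test_mse = test_mse[seq_len(epochs_run)]),
                 stop_reason = stop_reason,
                 best_epoch = best_epoch),
            class = "trained_network")
}

#' @export
print.trained_network <- function(x, ...) {
  h <- x$history
  cat("trained", paste(x$params$layer_sizes, collapse = "-"), "network:",
      nrow(h), "epochs, stop:", x$stop_reason, "\n")
  cat(sprintf("  best test MSE %.4g at epoch %d (final train MSE %.4g)\n",
              min(h$test_mse), x$best_epoch, h$train_mse[nrow(h)]))
  invisible(x)
}
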