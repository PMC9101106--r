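# shared fixtures; everything is generated in code, nothing on disk

# simulator with all randomness off, for exact-arithmetic checks
noise_free_params <- function(...) {
  sim_params(ref_sd = 0, signal_noise_sd = 0, temp_noise_sd = 0, ...)
}

# one full default-condition pipeline run (published protocol, seed 1),
# computed once and shared across test files
.run_cache <- new.env(parent = emptyenv())
default_run <- function() {
  if (is.null(.run_cache$run))
    .run_cache$run <- suppressWarnings(run_pipeline(pipeline_config(seed = 1)))
  .run_cache$run
}

# quick reduced-size pipeline config for plumbing tests
small_config <- function(seed = 7L) {
  pipeline_config(
    seed = seed, replicates = 2L, blank_replicates = 5L,
    concentration_config = train_config(max_epochs = 40L),
    reference_config = train_config(max_epochs = 40L,
                                    mse_stop_threshold = 0.01))
}

# independent least-squares oracle: solve the normal equations directly
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1L], slope = beta[2L])
}

# independent gradient oracle: central finite differences on the MSE loss
numeric_gradients <- function(params, x, y, h = 1e-6) {
  f <- function(p) mse_loss(y, nn_forward(p, x))
  gw <- lapply(seq_along(params$weights), function(l) {
    g <- params$weights[[l]]
    for (i in seq_along(g)) {
      up <- params; up$weights[[l]][i] <- up$weights[[l]][i] + h
      dn <- params; dn$weights[[l]][i] <- dn$weights[[l]][i] - h
      g[i] <- (f(up) - f(dn)) / (2 * h)
    }
    g
  })
  gb <- lapply(seq_along(params$biases), function(l) {
    g <- params$biases[[l]]
    for (i in seq_along(g)) {
      up <- params; up$biases[[l]][i] <- up$biases[[l]][i] + h
      dn <- params; dn$biases[[l]][i] <- dn$biases[[l]][i] - h
      g[i] <- (f(up) - f(dn)) / (2 * h)
    }
    g
  })
  list(weights = gw, biases = gb)
}
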