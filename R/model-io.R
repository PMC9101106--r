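#' Fit the two-input concentration model from sensor logs
#'
#' Convenience wrapper tying the preprocessing contract together: builds
#' regression arrays from the training and testing logs, fits min-max
#' normalization on the training portion only, applies it to both, and
#' trains the 2-20-16-1 network. The returned model object is
#' self-contained (network weights + normalization + target transform), so
#' prediction needs no training-time state.
#'
#' @param train,test sensor-log data frames (see [generate_dataset()],
#'   [split_dataset()]).
#' @param config a [train_config()]; the published protocol is learning
#'   rate 0.01 with a 5000-epoch cap.
#' @param target_transform `"log10"` (default) or `"identity"`; see
#'   [regression_data()].
#' @return An object of class `isfet_model`.
#' @export
train_concentration_model <- function(train, test,
                                      config = train_config(),
                                      target_transform = c("log10", "identity")) {
  target_transform <- match.arg(target_transform)
  rtr <- regression_data(train, target_transform)
  rte <- regression_data(test, target_transform)
  if (is.null(rtr$y)) stop("training log has no known concentrations", call. = FALSE)
  norm_x <- fit_norm_params(rtr$x)
  norm_y <- fit_norm_params(matrix(rtr$y, ncol = 1L))
  xtr <- minmax_normalize(rtr$x, norm_x)
  xte <- minmax_normalize(rte$x, norm_x)
  ytr <- minmax_normalize(matrix(rtr$y, ncol = 1L), norm_y)[, 1L]
  yte <- minmax_normalize(matrix(rte$y, ncol = 1L), norm_y)[, 1L]
  fit <- nn_train(xtr, ytr, xte, yte, concentration_net_layers(), config)
  new_isfet_model(fit, norm_x, norm_y, target_transform,
                  feature_names = c("delta_vgs_mv", "temperature_c"))
}

new_isfet_model <- function(fit, norm_x, norm_y, target_transform,
                            feature_names) {
  h <- fit$history
  structure(list(network = fit$params,
                 norm_x = norm_x, norm_y = norm_y,
                 target_transform = target_transform,
                 feature_names = feature_names,
                 history = h,
                 meta = list(stop_reason = fit$stop_reason,
                             best_epoch = fit$best_epoch,
                             epochs_run = nrow(h),
                             best_test_mse = min(h$test_mse),
                             final_train_mse = h$train_mse[nrow(h)])),
            class = "isfet_model")
}

#' @export
print.isfet_model <- function(x, ...) {
  cat("enzyme-ISFET regression model\n")
  cat("  features:", paste(x$feature_names, collapse = ", "),
      "| target transform:", x$target_transform, "\n")
  print(x$network)
  cat(sprintf("  trained %d epochs (stop: %s), best test MSE %.4g at epoch %d\n",
              x$meta$epochs_run, x$meta$stop_reason, x$meta$best_test_mse,
              x$meta$best_epoch))
  invisible(x)
}

#' Predict with a fitted model on raw-scale features
#'
#' Normalizes the raw features with the stored training-set parameters
#' (out-of-range values are clipped with a warning), runs the forward
#' pass, and returns either the normalized output or the denormalized,
#' back-transformed value on the original target scale.
#'
#' @param object an `isfet_model`.
#' @param newdata feature matrix on the raw scale, columns in
#'   `object$feature_names` order (a vector is accepted for single-feature
#'   models).
#' @param scale `"response"` (original target scale; molar concentration
#'   for `"log10"` models) or `"normalized"`.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.isfet_model <- function(object, newdata,
                                scale = c("response", "normalized"), ...) {
  scale <- match.arg(scale)
  x <- as_feature_matrix(newdata, object$network$layer_sizes[1L])
  xn <- minmax_normalize(x, object$norm_x)
  out <- nn_forward(object$network, xn)
  if (scale == "normalized") return(out)
  y <- denormalize(out, object$norm_y)
  if (object$target_transform == "log10") 10^y else y
}

#' Save / load a model as JSON
#'
#' The model file carries the layer sizes, every weight matrix (row-major
#' nested arrays) and bias vector, the feature and target normalization
#' ranges, the target-transform tag, and training metadata. Numbers are
#' written with 17 significant digits (exact for IEEE doubles), so a
#' loaded model reproduces forward outputs bit-identically.
#'
#' @param model an `isfet_model`.
#' @param path file path for the JSON model file.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the `isfet_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "isfet_model"))
  norm_as_list <- function(p) list(min = unname(p$min), max = unname(p$max),
                                   degenerate = unname(p$degenerate))
  obj <- list(format = "enzisfet-model",
              version = 1L,
              layer_sizes = model$network$layer_sizes,
              weights = model$network$weights,
              biases = model$network$biases,
              norm_x = norm_as_list(model$norm_x),
              norm_y = norm_as_list(model$norm_y),
              target_transform = model$target_transform,
              feature_names = model$feature_names,
              meta = model$meta)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format[1L], "enzisfet-model"))
    stop("not an enzisfet model file: ", path, call. = FALSE)
  sizes <- as.integer(obj$layer_sizes)
  L <- length(sizes) - 1L
  ## each weight entry simplifies back to a matrix in the written
  ## orientation; a 1 x k layer may come back as a bare vector
  w <- lapply(seq_len(L), function(l) {
    m <- obj$weights[[l]]
    matrix(as.numeric(if (is.matrix(m)) t(m) else m),
           sizes[l], sizes[l + 1L], byrow = TRUE)
  })
  b <- lapply(seq_len(L), function(l) as.numeric(obj$biases[[l]]))
  net <- structure(list(layer_sizes = sizes, weights = w, biases = b),
                   class = "network_params")
  restore_norm <- function(p, nms) structure(
    list(min = stats::setNames(as.numeric(p$min), nms),
         max = stats::setNames(as.numeric(p$max), nms),
         degenerate = stats::setNames(as.logical(p$degenerate), nms)),
    class = "norm_params")
  fn <- as.character(obj$feature_names)
  structure(list(network = net,
                 norm_x = restore_norm(obj$norm_x, fn),
                 norm_y = restore_norm(obj$norm_y, NULL),
                 target_transform = as.character(obj$target_transform),
                 feature_names = fn,
                 history = NULL,
                 meta = lapply(obj$meta, function(v) if (is.list(v)) v else v[1L])),
            class = "isfet_model")
}
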