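#' Fit per-column min-max normalization parameters
#'
#' Records each column's minimum and maximum on the original scale, the
#' state needed to map values to \[0, 1\] and back. A column whose min and
#' max coincide is degenerate: by default that is an error; with
#' `degenerate = "constant"` it is flagged and later mapped to 0 (and
#' inverted back to the constant), which is what lets a noise-free constant
#' target pass through the pipeline.
#'
#' @param x numeric matrix or data frame (columns are variables).
#' @param degenerate `"error"` or `"constant"`.
#' @return An object of class `norm_params` with fields `min`, `max`,
#'   `degenerate` (logical per column).
#' @export
fit_norm_params <- function(x, degenerate = c("error", "constant")) {
  degenerate <- match.arg(degenerate)
  x <- as.matrix(x)
  stopifnot(is.numeric(x), nrow(x) >= 1L)
  mins <- apply(x, 2L, min)
  maxs <- apply(x, 2L, max)
  flat <- maxs == mins
  if (any(flat) && degenerate == "error")
    stop("degenerate column(s) with max == min: ",
         paste(which(flat), collapse = ", "), call. = FALSE)
  structure(list(min = mins, max = maxs, degenerate = flat),
            class = "norm_params")
}

#' @export
print.norm_params <- function(x, ...) {
  cat("min-max normalization over", length(x$min), "column(s)\n")
  print(data.frame(min = x$min, max = x$max, degenerate = x$degenerate))
  invisible(x)
}

#' Min-max normalize to the unit interval
#'
#' Maps each value to (v - min) / (max - min). When `params` is supplied
#' the stored ranges are applied unchanged (no refit) -- the leakage-free
#' convention of normalizing held-out data with training-set parameters.
#' Values outside the fitted range are clipped into \[0, 1\] with a
#' warning; field readings may drift slightly outside calibration and are
#' better clipped than rejected.
#'
#' @inheritParams fit_norm_params
#' @param params a `norm_params` object, or `NULL` to fit from `x`.
#' @param clip clip out-of-range values (default) instead of letting them
#'   leave the unit interval.
#' @return A numeric matrix in \[0, 1\] with the `norm_params` used
#'   attached as attribute `"norm_params"`.
#' @seealso [denormalize()]
#' @export
minmax_normalize <- function(x, params = NULL,
                             degenerate = c("error", "constant"),
                             clip = TRUE) {
  x <- as.matrix(x)
  if (is.null(params)) params <- fit_norm_params(x, degenerate)
  stopifnot(inherits(params, "norm_params"), ncol(x) == length(params$min))
  span <- ifelse(params$degenerate, 1, params$max - params$min)
  out <- sweep(sweep(x, 2L, params$min, "-"), 2L, span, "/")
  if (clip && (any(out < 0) || any(out > 1))) {
    warning(sum(out < 0 | out > 1),
            " value(s) outside the fitted range were clipped to [0, 1]",
            call. = FALSE)
    out <- clamp(out, 0, 1)
  }
  attr(out, "norm_params") <- params
  out
}

#' Invert min-max normalization
#'
#' Maps unit-interval values back to the original scale,
#' v * (max - min) + min. Degenerate columns return their constant.
#'
#' @param x normalized matrix (or vector for single-column params).
#' @param params the `norm_params` used to normalize.
#' @return Matrix (or vector, matching the input shape) on the original
#'   scale.
#' @export
denormalize <- function(x, params) {
  stopifnot(inherits(params, "norm_params"))
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(params$min))
  span <- ifelse(params$degenerate, 0, params$max - params$min)
  out <- sweep(sweep(x, 2L, span, "*"), 2L, params$min, "+")
  if (vec) out[, 1L] else out
}

#' Augment a sensor log with additive white Gaussian noise
#'
#' Replicates every row `factor` times and adds independent zero-mean
#' Gaussian noise to the signal and temperature features; the ground-truth
#' concentration (the regression target) is never altered. This mimics the
#' thermal/electronic measurement noise of repeated reads and is how a
#' 200-row factorial design becomes a 2000-row training corpus.
#'
#' @param readings sensor-log `data.frame` (see [generate_dataset()]).
#' @param factor integer >= 1; output has exactly `factor * nrow(readings)`
#'   rows.
#' @param signal_sd noise SD on `delta_vgs_mv`, mV (>= 0).
#' @param temp_sd noise SD on `temperature_c`, degC (>= 0).
#' @param seed optional integer for a self-contained reproducible draw.
#' @return The augmented sensor log, with provenance columns `source_row`
#'   (row index in `readings`) and `origin = "augmented"`.
#' @export
awgn_augment <- function(readings, factor = 10L, signal_sd = 0.2,
                         temp_sd = 0.1, seed = NULL) {
  stopifnot(is.data.frame(readings), nrow(readings) >= 1L)
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1", call. = FALSE)
  if (signal_sd < 0 || temp_sd < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  idx <- rep(seq_len(nrow(readings)), each = factor)
  out <- readings[idx, , drop = FALSE]
  rownames(out) <- NULL
  n <- nrow(out)
  draw <- function() list(s = rnorm(n, 0, signal_sd), t = rnorm(n, 0, temp_sd))
  noise <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out$delta_vgs_mv <- out$delta_vgs_mv + noise$s
  out$temperature_c <- out$temperature_c + noise$t
  out$source_row <- idx
  out$origin <- "augmented"
  out
}

#' Split a sensor log into training and testing portions
#'
#' Disjoint, exhaustive random split. With stratification (the default)
#' each nominal-temperature stratum is split at the same fraction, so a
#' 2000-row log over four temperatures at 0.8 yields 1600/400 overall and
#' 400/100 per temperature.
#'
#' @inheritParams awgn_augment
#' @param train_fraction in (0, 1).
#' @param stratify_by_temperature split each `temperature_nominal` stratum
#'   separately.
#' @return `list(train = , test = )` of sensor-log data frames.
#' @export
split_dataset <- function(readings, train_fraction = 0.8,
                          stratify_by_temperature = TRUE, seed = NULL) {
  stopifnot(is.data.frame(readings))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  pick <- function() {
    if (stratify_by_temperature) {
      strata <- split(seq_len(nrow(readings)), readings$temperature_nominal)
      unlist(lapply(names(strata), function(nm) {
        i <- strata[[nm]]
        k <- round(train_fraction * length(i))
        if (k < 1L || k >= length(i))
          stop("stratum '", nm, "' (", length(i),
               " rows) is too small to split at fraction ", train_fraction,
               call. = FALSE)
        sample(i, k)
      }), use.names = FALSE)
    } else {
      k <- round(train_fraction * nrow(readings))
      if (k < 1L || k >= nrow(readings))
        stop("too few rows to split at fraction ", train_fraction, call. = FALSE)
      sample(seq_len(nrow(readings)), k)
    }
  }
  idx <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  list(train = readings[sort(idx), , drop = FALSE],
       test = readings[setdiff(seq_len(nrow(readings)), idx), , drop = FALSE])
}

#' Assemble regression arrays from a sensor log
#'
#' Extracts the feature matrix (signal response mV, temperature degC) and
#' the target vector. Concentration is regressed on the log10-molar scale
#' by default: the factorial design spans four decades, and on the raw
#' molar scale all but the top level collapse into the bottom tenth of the
#' unit interval. `"identity"` keeps the raw scale for comparison.
#'
#' @inheritParams awgn_augment
#' @param target_transform `"log10"` or `"identity"`.
#' @return `list(x = matrix, y = numeric or NULL, target_transform = )`.
#'   `y` is `NULL` for logs of blank reads.
#' @export
regression_data <- function(readings, target_transform = c("log10", "identity")) {
  target_transform <- match.arg(target_transform)
  stopifnot(is.data.frame(readings))
  x <- cbind(delta_vgs_mv = readings$delta_vgs_mv,
             temperature_c = readings$temperature_c)
  y <- if (all(is.na(readings$concentration_m))) NULL
       else if (target_transform == "log10") log10(readings$concentration_m)
       else readings$concentration_m
  list(x = x, y = y, target_transform = target_transform)
}
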