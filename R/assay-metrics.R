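#' Percent enzyme inhibition from paired signal responses
#'
#' The assay's core readout: the absolute relative drop of the
#' with-pesticide signal against the no-pesticide reference,
#' |ref - with| / |ref| x 100.
#'
#' @param ref reference signal response (no carbaryl), mV; must be
#'   non-zero.
#' @param with_carbaryl signal response with carbaryl, mV.
#' @return Percent inhibition (>= 0).
#' @examples
#' percent_inhibition(45.35, 28.78) # 36.54 percent
#' @export
percent_inhibition <- function(ref, with_carbaryl) {
  stopifnot(is.numeric(ref), is.numeric(with_carbaryl))
  if (any(ref == 0)) stop("reference signal must be non-zero", call. = FALSE)
  abs(ref - with_carbaryl) / abs(ref) * 100
}

#' Three-sigma limit-of-detection check
#'
#' The detection criterion: three standard deviations of the reference
#' signal added to the signal at the lowest tested concentration must stay
#' below the reference signal itself. With the published figures
#' (SD 1.6 mV, minimum carbaryl signal 28.78 mV, reference 45.35 mV) the
#' three-sigma term is 4.8 mV and the criterion passes.
#'
#' @param sd standard deviation of the reference signal, mV (>= 0).
#' @param min_carbaryl_signal signal at the lowest tested concentration,
#'   mV.
#' @param reference no-carbaryl reference signal, mV.
#' @return An object of class `lod_result`: `sd`, `three_sd`,
#'   `min_carbaryl_signal`, `lod_signal` (= 3 sd + minimum signal),
#'   `reference`, and the pass flag `passes`.
#' @export
lod_check <- function(sd, min_carbaryl_signal, reference) {
  stopifnot(sd >= 0, is.finite(min_carbaryl_signal), is.finite(reference))
  lod_signal <- 3 * sd + min_carbaryl_signal
  structure(list(sd = sd, three_sd = 3 * sd,
                 min_carbaryl_signal = min_carbaryl_signal,
                 lod_signal = lod_signal, reference = reference,
                 passes = lod_signal < reference),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("LOD signal = 3 x %.4g + %.4g = %.4g mV vs reference %.4g mV: %s\n",
              x$sd, x$min_carbaryl_signal, x$lod_signal, x$reference,
              if (x$passes) "detectable" else "not detectable"))
  invisible(x)
}

#' Ordinary least-squares calibration line
#'
#' Fits y = slope * x + intercept by OLS (via [stats::lm()]) and reports
#' the coefficient of determination 1 - SSres / SStot. Used for the pH
#' sensitivity line (x in pH units) and the inhibition calibration line
#' (x in ln molar).
#'
#' @param x,y numeric vectors; `x` needs at least two distinct values.
#' @param domain optional tag recording what `x` is (`"pH"`,
#'   `"ln-concentration"`, ...).
#' @return An object of class `calibration_line`: `slope`, `intercept`,
#'   `r_squared`, `domain`.
#' @export
fit_line <- function(x, y, domain = NA_character_) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(unique(x)) < 2L)
    stop("x must contain at least two distinct values", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
                 domain = domain),
            class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("y = %.6g x + %.6g (R^2 = %.4g%s)\n", x$slope, x$intercept,
              x$r_squared,
              if (is.na(x$domain)) "" else paste0(", x: ", x$domain)))
  invisible(x)
}

#' Is a pH sensitivity acceptable?
#'
#' A sensor qualifies for the inhibition assay when its pH sensitivity
#' lies in the inclusive 45-55 mV/pH band.
#'
#' @param slope fitted sensitivity, mV per pH unit.
#' @return Logical.
#' @export
sensitivity_acceptable <- function(slope) {
  slope >= 45 & slope <= 55
}

#' Regression evaluation metrics
#'
#' MSE (mean squared residual), MAE (mean absolute residual), the
#' population variance of the observed targets, and the coefficient of
#' determination in its variance form, R^2 = (Var(y) - MSE) / Var(y).
#' That formula can go negative when the predictor does worse than the
#' mean; the value is reported as-is with a warning rather than clamped.
#' With zero target variance R^2 is undefined and returned as `NA` with a
#' warning.
#'
#' @param y observed (normalized) targets.
#' @param yhat predictions, same length.
#' @return An object of class `regression_metrics`: `mse`, `mae`,
#'   `var_y`, `r_squared`, `n`.
#' @export
evaluate_metrics <- function(y, yhat) {
  if (length(y) == 0L) stop("empty input", call. = FALSE)
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  mse <- mse_loss(y, yhat)
  mae <- mean(abs(y - yhat))
  var_y <- mean((y - mean(y))^2)
  if (var_y == 0) {
    warning("zero target variance: R^2 is undefined", call. = FALSE)
    r2 <- NA_real_
  } else {
    r2 <- (var_y - mse) / var_y
    if (r2 < 0)
      warning("R^2 is negative (MSE exceeds the target variance)",
              call. = FALSE)
  }
  structure(list(mse = mse, mae = mae, var_y = var_y, r_squared = r2,
                 n = length(y)),
            class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf("n = %d: MSE %.4g, MAE %.4g, Var %.4g, R^2 %.4g\n",
              x$n, x$mse, x$mae, x$var_y, x$r_squared))
  invisible(x)
}
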