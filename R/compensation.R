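#' Fit the single-input temperature-to-reference model
#'
#' Trains the 1-10-5-1 network mapping solution temperature to the
#' no-carbaryl reference signal, the first stage of signal compensation.
#' The blank log is split 80/20 (stratified over temperature), normalized
#' on the training portion, and trained with the published single-input
#' protocol: learning rate 0.01, epoch cap 3000, and an early stop when
#' the training MSE reaches 0.01 on the normalized scale.
#'
#' A noise-free blank set with no temperature drift has a constant target;
#' that degenerate column is carried through normalization as a constant
#' (see [fit_norm_params()]) and the model reproduces it exactly.
#'
#' @param blanks sensor log of blank reads ([generate_blanks()] or a read
#'   CSV): `concentration_m` must be all `NA`, and at least two distinct
#'   temperatures must be present.
#' @param config a [train_config()].
#' @param split_fraction,split_seed train/test split of the blanks.
#' @return An `isfet_model` whose single feature is `temperature_c` and
#'   whose target is the reference signal in mV (identity transform).
#' @seealso [predict_reference()], [calibration_voltage()]
#' @export
fit_reference_model <- function(blanks,
                                config = train_config(max_epochs = 3000L,
                                                      mse_stop_threshold = 0.01),
                                split_fraction = 0.8, split_seed = 1L) {
  stopifnot(is.data.frame(blanks))
  if (!all(is.na(blanks$concentration_m)))
    stop("blank log contains carbaryl readings; reference fitting needs ",
         "no-pesticide reads only", call. = FALSE)
  if (length(unique(blanks$temperature_nominal)) < 2L)
    stop("blank reads span a single temperature; at least two are needed",
         call. = FALSE)
  sp <- split_dataset(blanks, split_fraction, TRUE, seed = split_seed)
  xtr <- matrix(sp$train$temperature_c, ncol = 1L,
                dimnames = list(NULL, "temperature_c"))
  xte <- matrix(sp$test$temperature_c, ncol = 1L,
                dimnames = list(NULL, "temperature_c"))
  ytr <- matrix(sp$train$delta_vgs_mv, ncol = 1L)
  yte <- matrix(sp$test$delta_vgs_mv, ncol = 1L)
  norm_x <- fit_norm_params(xtr)
  norm_y <- fit_norm_params(ytr, degenerate = "constant")
  fit <- nn_train(minmax_normalize(xtr, norm_x),
                  minmax_normalize(ytr, norm_y)[, 1L],
                  minmax_normalize(xte, norm_x),
                  minmax_normalize(yte, norm_y)[, 1L],
                  reference_net_layers(), config)
  new_isfet_model(fit, norm_x, norm_y, target_transform = "identity",
                  feature_names = "temperature_c")
}

#' Predicted reference signal at a temperature
#'
#' @param model the reference model from [fit_reference_model()].
#' @param temperature solution temperature(s), degC.
#' @return Predicted no-carbaryl signal response(s), mV.
#' @export
predict_reference <- function(model, temperature) {
  stopifnot(inherits(model, "isfet_model"),
            identical(model$feature_names, "temperature_c"))
  predict(model, matrix(temperature, ncol = 1L))
}

#' Per-sensor calibration voltage
#'
#' The difference between what a particular sensor's blank read actually
#' measures and what the reference model predicts at the same temperature.
#' The comparison is an additive offset in mV (not a ratio). Several blank
#' reads may be supplied (the triplicate protocol); their offsets are
#' averaged.
#'
#' @param measured_blank blank-read signal(s) of the sensor in hand, mV.
#' @param temperature temperature(s) of those reads, degC (recycled if
#'   scalar).
#' @param model the fitted reference model.
#' @return Calibration voltage, mV (positive when the sensor reads high).
#' @export
calibration_voltage <- function(measured_blank, temperature, model) {
  stopifnot(is.numeric(measured_blank), length(measured_blank) >= 1L)
  pred <- predict_reference(model, rep_len(temperature, length(measured_blank)))
  mean(measured_blank - pred)
}

#' Bundle the compensation state for prediction
#'
#' @param model the reference model ([fit_reference_model()]).
#' @param calibration_voltage per-sensor offset in mV
#'   ([calibration_voltage()]).
#' @param matrix_correction additive correction in mV for
#'   vegetable-extract samples, 0 for buffer; see
#'   [matrix_correction_from_inhibition_gap()].
#' @return An object of class `calibration_state`.
#' @export
calibration_state <- function(model, calibration_voltage,
                              matrix_correction = 0) {
  stopifnot(inherits(model, "isfet_model"),
            is.finite(calibration_voltage))
  if (matrix_correction < 0)
    stop("matrix_correction must be >= 0", call. = FALSE)
  structure(list(model = model,
                 calibration_voltage = calibration_voltage,
                 matrix_correction = matrix_correction),
            class = "calibration_state")
}

#' @export
print.calibration_state <- function(x, ...) {
  cat(sprintf("calibration: voltage %+.4g mV, matrix correction %+.4g mV\n",
              x$calibration_voltage, x$matrix_correction))
  invisible(x)
}

#' Compensate a raw signal response
#'
#' Subtracts the per-sensor calibration voltage and the matrix
#' correction, yielding the signal the population-calibrated,
#' buffer-trained concentration model expects. The matrix correction is
#' subtracted because an extract-diluted sample inhibits less than a
#' buffer-diluted one at the same concentration, so its signal reads
#' high; lowering it by the signal equivalent of the inhibition gap
#' makes the corrected extract reading match the buffer reading that
#' encodes the same inhibition.
#'
#' @param delta_vgs raw signal response(s), mV.
#' @param state a [calibration_state()]; `matrix_correction` is the
#'   non-negative magnitude of the extract excess, mV.
#' @return Compensated signal(s), mV.
#' @export
compensate_signal <- function(delta_vgs, state) {
  stopifnot(inherits(state, "calibration_state"))
  delta_vgs - state$calibration_voltage - state$matrix_correction
}

#' Signal correction implied by an inhibition gap
#'
#' Extract-diluted samples show 2.68-3.24 percent less enzyme inhibition
#' than buffer-diluted ones; at 0.45 mV per percent inhibition that is a
#' 1.206-1.458 mV correction to the input signal. When the gap for a
#' sample is unknown the midpoint of the published range (2.96 percent,
#' i.e. 1.332 mV) is a reasonable default.
#'
#' @param gap inhibition deficit, percent (>= 0).
#' @param mv_per_percent signal equivalent of one percent inhibition,
#'   mV per percent.
#' @return Correction in mV.
#' @examples
#' matrix_correction_from_inhibition_gap(2.68) # 1.206 mV
#' @export
matrix_correction_from_inhibition_gap <- function(gap, mv_per_percent = 0.45) {
  if (any(gap < 0)) stop("gap must be >= 0", call. = FALSE)
  gap * mv_per_percent
}
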