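#' Simulator calibration constants for the enzyme-ISFET generator
#'
#' Bundles every empirical constant the response simulator is built from:
#' the pH sensitivity line of the bare sensor, the mean and spread of the
#' no-carbaryl reference signal at 25 degC, the inhibition-vs-log-concentration
#' calibration line, temperature coefficients, the vegetable-extract matrix
#' offset range, the mV-per-percent-inhibition equivalence, and the
#' per-reading noise magnitudes.
#'
#' The defaults reproduce the sensor's printed calibration behaviour:
#' a pH sensitivity of 49.86 mV/pH with intercept 418.98 mV, a reference
#' signal of 45.35 +/- 1.6 mV at 25 degC, an inhibition line of
#' 6.6098 ln(c) + 134.62 percent (linear in ln molarity over 1e-6 to 1e-4 M,
#' extrapolated then clamped outside that range), a vegetable-extract
#' inhibition deficit of 2.68-3.24 percent, and 0.45 mV per percent
#' inhibition. The two temperature coefficients and the noise standard
#' deviations are not printed anywhere and are configurable stand-ins
#' (see the methods vignette); the pipeline must work for any values of
#' them, including zero.
#'
#' @param ph_slope pH sensitivity, mV per pH unit. An acceptable sensor
#'   lies in the 45-55 mV/pH band; values outside it trigger a warning,
#'   not an error, so degraded sensors can still be simulated.
#' @param ph_intercept intercept of the pH response line, mV.
#' @param ref_mean_25c mean no-carbaryl reference signal at 25 degC, mV.
#' @param ref_sd standard deviation of the reference signal across blank
#'   reads, mV. Must be >= 0.
#' @param ref_temp_coeff linear drift of the reference signal with solution
#'   temperature, mV per degC (applied about 25 degC).
#' @param inhib_slope slope of the enzyme-inhibition line, percent per
#'   ln(molar).
#' @param inhib_intercept intercept of the inhibition line, percent.
#' @param inhib_temp_coeff linear temperature adjustment of inhibition,
#'   percent per degC (applied about 25 degC).
#' @param matrix_offset_range length-2 numeric, low/high of the uniform
#'   inhibition deficit (percent) of extract-diluted versus buffer-diluted
#'   samples.
#' @param mv_per_percent signal equivalent of one percent enzyme
#'   inhibition, mV.
#' @param signal_noise_sd per-reading additive Gaussian noise on the
#'   signal, mV. Must be >= 0.
#' @param temp_noise_sd per-reading additive Gaussian noise on the recorded
#'   temperature, degC. Must be >= 0.
#' @param seed optional integer; when set, [generate_dataset()] and
#'   [generate_blanks()] default to it so a parameter set pins down its
#'   datasets completely.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @seealso [generate_dataset()], [carbaryl_signal()], [reference_signal()]
#' @examples
#' p <- sim_params()
#' p$ref_mean_25c
#' sim_params(signal_noise_sd = 0, ref_sd = 0) # noise-free generator
#' @export
sim_params <- function(ph_slope = 49.86,
                       ph_intercept = 418.98,
                       ref_mean_25c = 45.35,
                       ref_sd = 1.6,
                       ref_temp_coeff = 0.3,
                       inhib_slope = 6.6098,
                       inhib_intercept = 134.62,
                       inhib_temp_coeff = 0.4,
                       matrix_offset_range = c(2.68, 3.24),
                       mv_per_percent = 0.45,
                       signal_noise_sd = 0.2,
                       temp_noise_sd = 0.1,
                       seed = NULL) {
  stopifnot(is.numeric(ph_slope), length(ph_slope) == 1L,
            is.numeric(matrix_offset_range), length(matrix_offset_range) == 2L)
  if (ref_sd < 0 || signal_noise_sd < 0 || temp_noise_sd < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  if (matrix_offset_range[1] > matrix_offset_range[2])
    stop("matrix_offset_range must be ordered (low, high)", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  if (ph_slope < 45 || ph_slope > 55)
    warning("ph_slope ", ph_slope,
            " mV/pH is outside the acceptable 45-55 mV/pH sensitivity band",
            call. = FALSE)
  structure(
    list(ph_slope = ph_slope, ph_intercept = ph_intercept,
         ref_mean_25c = ref_mean_25c, ref_sd = ref_sd,
         ref_temp_coeff = ref_temp_coeff,
         inhib_slope = inhib_slope, inhib_intercept = inhib_intercept,
         inhib_temp_coeff = inhib_temp_coeff,
         matrix_offset_range = as.numeric(matrix_offset_range),
         mv_per_percent = mv_per_percent,
         signal_noise_sd = signal_noise_sd, temp_noise_sd = temp_noise_sd,
         seed = seed),
    class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Enzyme-ISFET simulator parameters\n")
  cat(sprintf("  pH line:          %.4g * pH + %.4g mV\n", x$ph_slope, x$ph_intercept))
  cat(sprintf("  reference @25C:   %.4g +/- %.3g mV (%+.3g mV/degC)\n",
              x$ref_mean_25c, x$ref_sd, x$ref_temp_coeff))
  cat(sprintf("  inhibition line:  %.5g ln(c) + %.5g %% (%+.3g %%/degC)\n",
              x$inhib_slope, x$inhib_intercept, x$inhib_temp_coeff))
  cat(sprintf("  extract deficit:  %.3g-%.3g %% (%.3g mV/%%)\n",
              x$matrix_offset_range[1], x$matrix_offset_range[2], x$mv_per_percent))
  cat(sprintf("  noise:            signal %.3g mV, temperature %.3g degC\n",
              x$signal_noise_sd, x$temp_noise_sd))
  if (!is.null(x$seed)) cat("  seed:            ", x$seed, "\n")
  invisible(x)
}

#' Serialize / restore simulator parameters
#'
#' `sim_params` round-trips through a plain named list suitable for a
#' YAML or JSON configuration block.
#'
#' @param params a `sim_params` object.
#' @param x a named list as produced by `as.list()` on a `sim_params`
#'   object (or read back from YAML/JSON).
#' @return `sim_params_to_list()` returns a plain list;
#'   `sim_params_from_list()` returns a validated `sim_params` object.
#' @export
sim_params_to_list <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  unclass(params)
}

#' @rdname sim_params_to_list
#' @export
sim_params_from_list <- function(x) {
  stopifnot(is.list(x))
  known <- names(formals(sim_params))
  do.call(sim_params, x[intersect(names(x), known)])
}
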