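#' @importFrom stats rnorm runif
NULL

## x first: pmin/pmax take the result's attributes (incl. dim) from their
## first argument
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Deterministic pH response of the bare ISFET sensor
#'
#' Evaluates the sensor's linear pH calibration, signal = slope * pH +
#' intercept. Noise, if wanted, is the caller's business.
#'
#' @param ph pH values in \[0, 14\].
#' @param params a [sim_params()] object.
#' @return Signal response in mV, same length as `ph`.
#' @examples
#' ph_response(7) # 768.00 mV with the default calibration
#' @export
ph_response <- function(ph, params = sim_params()) {
  stopifnot(inherits(params, "sim_params"), is.numeric(ph))
  if (any(ph < 0 | ph > 14))
    stop("pH must lie in [0, 14]", call. = FALSE)
  params$ph_slope * ph + params$ph_intercept
}

#' Expected (noise-free) reference signal at a solution temperature
#'
#' The mean no-carbaryl signal response: `ref_mean_25c` plus the linear
#' temperature drift about 25 degC.
#'
#' @inheritParams ph_response
#' @param temperature solution temperature(s), degC.
#' @return mV, same length as `temperature`.
#' @export
expected_reference <- function(temperature, params = sim_params()) {
  stopifnot(inherits(params, "sim_params"), is.numeric(temperature),
            all(is.finite(temperature)))
  params$ref_mean_25c + params$ref_temp_coeff * (temperature - 25)
}

#' Draw no-carbaryl reference signals
#'
#' Samples blank (no pesticide) signal responses from
#' Normal(expected_reference(T), ref_sd^2). With `ref_sd = 0` the mean is
#' returned exactly. Draws come from the current RNG state; wrap in
#' [withr::with_seed()] (or set `params$seed` upstream) for reproducibility.
#'
#' @inheritParams expected_reference
#' @param n number of draws per temperature value; with a scalar
#'   `temperature` and `n > 1` a vector of `n` draws is returned.
#' @return Reference signal draws in mV.
#' @export
reference_signal <- function(temperature, params = sim_params(), n = 1L) {
  mu <- expected_reference(temperature, params)
  if (length(mu) == 1L && n > 1L) mu <- rep(mu, n)
  if (params$ref_sd == 0) return(mu)
  rnorm(length(mu), mean = mu, sd = params$ref_sd)
}

## inhibition before the [0, 100] clamp, so matrix offsets can be applied
## first (clamp comes after all adjustments)
inhibition_raw <- function(concentration, temperature, params) {
  params$inhib_slope * log(concentration) + params$inhib_intercept +
    params$inhib_temp_coeff * (temperature - 25)
}

#' Percent enzyme inhibition implied by a carbaryl concentration
#'
#' Evaluates the inhibition calibration line, linear in ln(concentration),
#' with its temperature adjustment, clamped to \[0, 100\] percent. The
#' printed line holds over 1e-6 to 1e-4 M; outside that range this is an
#' extrapolation (then clamped), which is what lets the generator cover the
#' full 1e-7 to 1e-3 M design.
#'
#' @inheritParams expected_reference
#' @param concentration carbaryl concentration(s), molar; must be > 0.
#' @return Percent inhibition in \[0, 100\].
#' @examples
#' inhibition_from_concentration(1e-5) # about 58.5 percent at 25 degC
#' @export
inhibition_from_concentration <- function(concentration, temperature = 25,
                                          params = sim_params()) {
  stopifnot(inherits(params, "sim_params"), is.numeric(concentration))
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("concentration must be finite and > 0", call. = FALSE)
  clamp(inhibition_raw(concentration, temperature, params), 0, 100)
}

#' Simulate the signal response of a carbaryl-exposed sensor
#'
#' Inverts the enzyme-inhibition readout: the carbaryl signal is the
#' expected reference signal at the solution temperature scaled by
#' (1 - inhibition/100), plus per-reading Gaussian noise of
#' `signal_noise_sd`. For `matrix = "extract"` an inhibition deficit drawn
#' uniformly from `matrix_offset_range` is subtracted before the clamp,
#' reproducing the lower inhibition (hence higher signal) of
#' vegetable-extract-diluted samples.
#'
#' The blank-to-blank spread `ref_sd` is deliberately not applied here: it
#' describes variability across blank reads/sensors, not within one
#' sensor's measurement series (see the methods vignette).
#'
#' @inheritParams inhibition_from_concentration
#' @param matrix `"buffer"` (PBS-diluted) or `"extract"`
#'   (vegetable-extract-diluted).
#' @return Signal response(s) with carbaryl, mV. Stochastic unless
#'   `signal_noise_sd = 0` and `matrix = "buffer"` (the extract offset is
#'   always a draw).
#' @export
carbaryl_signal <- function(concentration, temperature = 25,
                            matrix = c("buffer", "extract"),
                            params = sim_params()) {
  matrix <- match.arg(matrix)
  stopifnot(inherits(params, "sim_params"))
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("concentration must be finite and > 0", call. = FALSE)
  n <- max(length(concentration), length(temperature))
  inhib <- inhibition_raw(concentration, temperature, params)
  if (matrix == "extract")
    inhib <- inhib - runif(n, params$matrix_offset_range[1],
                           params$matrix_offset_range[2])
  inhib <- clamp(inhib, 0, 100)
  sig <- expected_reference(temperature, params) * (1 - inhib / 100)
  if (params$signal_noise_sd > 0)
    sig <- sig + rnorm(n, 0, params$signal_noise_sd)
  sig
}

#' Generate a full factorial sensor-log table
#'
#' Builds the measurement design the training data emulate: every
#' combination of concentration x temperature x replicate, with the
#' generating concentration recorded as ground truth. The default design
#' (5 concentrations from 1e-7 to 1e-3 M, temperatures 20/25/30/35 degC,
#' 10 replicates) yields 200 rows.
#'
#' @inheritParams carbaryl_signal
#' @param concentrations carbaryl concentrations, molar.
#' @param temperatures solution temperatures, degC.
#' @param replicates replicate count per cell, >= 1.
#' @param seed integer seed; defaults to `params$seed`. When non-NULL the
#'   table is fully reproducible and the caller's RNG state is untouched.
#' @return A `data.frame` with columns `delta_vgs_mv`, `temperature_c`,
#'   `temperature_nominal`, `matrix`, `concentration_m`, `replicate`.
#'   `temperature_nominal` is the design temperature (used later for
#'   stratified splitting); `temperature_c` is what the thermistor would
#'   log and here equals the nominal value until augmentation adds noise.
#' @examples
#' d <- generate_dataset(params = sim_params(seed = 1))
#' nrow(d) # 200
#' @export
generate_dataset <- function(concentrations = 10^(-7:-3),
                             temperatures = c(20, 25, 30, 35),
                             replicates = 10L,
                             matrix = c("buffer", "extract"),
                             params = sim_params(),
                             seed = params$seed) {
  matrix <- match.arg(matrix)
  if (length(concentrations) == 0L || length(temperatures) == 0L)
    stop("concentrations and temperatures must be non-empty", call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  grid <- expand.grid(concentration_m = concentrations,
                      temperature_c = temperatures,
                      replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE)
  draw <- function() carbaryl_signal(grid$concentration_m, grid$temperature_c,
                                     matrix = matrix, params = params)
  sig <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  data.frame(delta_vgs_mv = sig,
             temperature_c = grid$temperature_c,
             temperature_nominal = grid$temperature_c,
             matrix = matrix,
             concentration_m = grid$concentration_m,
             replicate = grid$replicate,
             stringsAsFactors = FALSE)
}

#' Generate blank (no-carbaryl) reference reads
#'
#' Reference reads across temperatures, drawn with the blank-to-blank
#' spread `ref_sd`; these are the training material for the single-input
#' temperature-to-reference model used in signal compensation.
#'
#' @inheritParams generate_dataset
#' @return A sensor-log `data.frame` like [generate_dataset()]'s, with
#'   `concentration_m = NA` marking blank reads.
#' @export
generate_blanks <- function(temperatures = c(20, 25, 30, 35),
                            replicates = 10L,
                            params = sim_params(),
                            seed = params$seed) {
  if (length(temperatures) == 0L) stop("temperatures must be non-empty", call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  grid <- expand.grid(temperature_c = temperatures,
                      replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE)
  draw <- function() reference_signal(grid$temperature_c, params)
  sig <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  data.frame(delta_vgs_mv = sig,
             temperature_c = grid$temperature_c,
             temperature_nominal = grid$temperature_c,
             matrix = "buffer",
             concentration_m = NA_real_,
             replicate = grid$replicate,
             stringsAsFactors = FALSE)
}

#' Read and write delimited sensor logs
#'
#' Sensor logs are plain CSV with header
#' `delta_vgs_mv,temperature_c,matrix,concentration_m,replicate`; molar
#' concentrations are written in scientific notation and blank reads carry
#' an empty concentration field.
#'
#' @param readings a sensor-log `data.frame`.
#' @param path file path.
#' @return `read_sensor_log()` returns the sensor-log `data.frame` (with a
#'   `temperature_nominal` column reconstructed as `temperature_c` when the
#'   file does not carry one); `write_sensor_log()` returns `path`
#'   invisibly.
#' @export
write_sensor_log <- function(readings, path) {
  stopifnot(is.data.frame(readings))
  out <- data.frame(
    delta_vgs_mv = readings$delta_vgs_mv,
    temperature_c = readings$temperature_c,
    matrix = readings$matrix,
    concentration_m = ifelse(is.na(readings$concentration_m), "",
                             format(readings$concentration_m, scientific = TRUE,
                                    digits = 15, trim = TRUE)),
    replicate = readings$replicate)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sensor_log
#' @export
read_sensor_log <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(delta_vgs_mv = "numeric",
                                      temperature_c = "numeric",
                                      matrix = "character",
                                      concentration_m = "numeric",
                                      replicate = "integer"))
  if (is.null(d$temperature_nominal)) d$temperature_nominal <- d$temperature_c
  d[c("delta_vgs_mv", "temperature_c", "temperature_nominal", "matrix",
      "concentration_m", "replicate")]
}
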