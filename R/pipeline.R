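#' End-to-end pipeline configuration
#'
#' One seeded configuration object drives the whole workflow: simulate the
#' factorial sensor log, augment it with measurement noise, split,
#' train the single-input reference network and the two-input
#' concentration network, calibrate, and evaluate. Every random draw in
#' [run_pipeline()] derives deterministically from `seed`.
#'
#' @param seed global integer seed.
#' @param sim a [sim_params()] object.
#' @param concentrations,temperatures,replicates the factorial measurement
#'   design (defaults: 5 decades x 4 temperatures x 10 replicates = 200
#'   rows).
#' @param augment_factor AWGN replication factor (10 turns 200 rows into
#'   2000).
#' @param augment_signal_sd,augment_temp_sd AWGN magnitudes; default to
#'   the simulator's per-reading noise SDs.
#' @param train_fraction,stratify train/test split controls.
#' @param target_transform `"log10"` (default) or `"identity"`.
#' @param concentration_config [train_config()] for the 2-20-16-1 network
#'   (published protocol: learning rate 0.01, 5000-epoch cap).
#' @param reference_config [train_config()] for the 1-10-5-1 network
#'   (learning rate 0.01, 3000-epoch cap, MSE stop 0.01).
#' @param blank_replicates blank reads per temperature for the reference
#'   corpus; 50 x 4 temperatures matches the 200-row base corpus of the
#'   concentration model before the same x10 augmentation.
#' @param calibration_reads number of blank reads averaged for the
#'   per-sensor calibration voltage (triplicate by default).
#' @return An object of class `pipeline_config` (a nested list).
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_params(),
                            concentrations = 10^(-7:-3),
                            temperatures = c(20, 25, 30, 35),
                            replicates = 10L,
                            augment_factor = 10L,
                            augment_signal_sd = sim$signal_noise_sd,
                            augment_temp_sd = sim$temp_noise_sd,
                            train_fraction = 0.8,
                            stratify = TRUE,
                            target_transform = "log10",
                            concentration_config = train_config(),
                            reference_config = train_config(max_epochs = 3000L,
                                                            mse_stop_threshold = 0.01),
                            blank_replicates = 50L,
                            calibration_reads = 3L) {
  structure(list(seed = as.integer(seed), sim = sim,
                 concentrations = concentrations,
                 temperatures = temperatures,
                 replicates = as.integer(replicates),
                 augment_factor = as.integer(augment_factor),
                 augment_signal_sd = augment_signal_sd,
                 augment_temp_sd = augment_temp_sd,
                 train_fraction = train_fraction, stratify = stratify,
                 target_transform = target_transform,
                 concentration_config = concentration_config,
                 reference_config = reference_config,
                 blank_replicates = as.integer(blank_replicates),
                 calibration_reads = as.integer(calibration_reads)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Scalar fields and the simulator block round-trip through a single YAML
#' file; unspecified fields keep their defaults.
#'
#' @param path YAML file path.
#' @param config a [pipeline_config()].
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), setdiff(names(formals(pipeline_config)),
                                            c("sim", "concentration_config",
                                              "reference_config")))]
  if (!is.null(raw$sim)) args$sim <- sim_params_from_list(raw$sim)
  tc <- function(x) do.call(train_config,
                            x[intersect(names(x), names(formals(train_config)))])
  if (!is.null(raw$concentration_config))
    args$concentration_config <- tc(raw$concentration_config)
  if (!is.null(raw$reference_config))
    args$reference_config <- tc(raw$reference_config)
  do.call(pipeline_config, args)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- unclass(config)
  out$sim <- sim_params_to_list(config$sim)
  out$concentration_config <- unclass(config$concentration_config)
  out$reference_config <- unclass(config$reference_config)
  yaml::write_yaml(out, path)
  invisible(path)
}

## fixed offsets give each pipeline stage an independent, reproducible
## RNG stream derived from the one global seed (kept well below 2^31)
stage_seed <- function(config, k) (config$seed %% 1000000L) * 1000L + k

#' Run the full simulate-train-calibrate-evaluate pipeline
#'
#' Executes, in order: factorial simulation of the sensor log, AWGN
#' augmentation, the stratified train/test split, training of the
#' single-input reference network on an independently generated and
#' augmented blank corpus, training of the two-input concentration
#' network, per-sensor calibration from averaged blank reads, and
#' evaluation of the concentration model on the held-out split
#' (normalized scale and log10-molar scale).
#'
#' The held-out evaluation scores the model directly on the test features:
#' the simulated corpus is the population-reference sensor itself, whose
#' true calibration voltage is zero, so no per-sensor compensation enters
#' the headline metrics. Compensation is applied at prediction time for
#' field sensors via [predict_concentration()].
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the sensor logs (CSV),
#'   both model files (JSON) and the report (JSON) are written there.
#' @return An object of class `pipeline_result`: the two models, the
#'   calibration state, the split data, and `report` (a plain list with
#'   dataset counts, training summaries, the evaluation metrics and the
#'   seeds used).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ## 1. simulate + augment + split the carbaryl corpus
  raw <- generate_dataset(config$concentrations, config$temperatures,
                          config$replicates, "buffer", config$sim,
                          seed = stage_seed(config, 1L))
  aug <- awgn_augment(raw, config$augment_factor, config$augment_signal_sd,
                      config$augment_temp_sd, seed = stage_seed(config, 2L))
  sp <- split_dataset(aug, config$train_fraction, config$stratify,
                      seed = stage_seed(config, 3L))
  ## 2. blank corpus + reference model (independent augmentation stream)
  blanks <- generate_blanks(config$temperatures, config$blank_replicates,
                            config$sim, seed = stage_seed(config, 4L))
  blanks_aug <- awgn_augment(blanks, config$augment_factor,
                             config$augment_signal_sd, config$augment_temp_sd,
                             seed = stage_seed(config, 5L))
  ref_cfg <- config$reference_config
  ref_cfg$seed <- stage_seed(config, 6L)
  ref_model <- fit_reference_model(blanks_aug, ref_cfg,
                                   config$train_fraction,
                                   split_seed = stage_seed(config, 7L))
  ## 3. concentration model
  conc_cfg <- config$concentration_config
  conc_cfg$seed <- stage_seed(config, 8L)
  model <- train_concentration_model(sp$train, sp$test, conc_cfg,
                                     config$target_transform)
  ## 4. per-sensor calibration from averaged blank reads at 25 degC
  cal_reads <- withr::with_seed(stage_seed(config, 9L),
    reference_signal(25, config$sim, n = config$calibration_reads))
  cal_v <- calibration_voltage(cal_reads, 25, ref_model)
  calibration <- calibration_state(ref_model, cal_v)
  ## 5. evaluate on the held-out split
  rte <- regression_data(sp$test, config$target_transform)
  yhat_norm <- predict(model, rte$x, scale = "normalized")
  y_norm <- minmax_normalize(matrix(rte$y, ncol = 1L), model$norm_y)[, 1L]
  metrics_norm <- evaluate_metrics(y_norm, yhat_norm)
  yhat_log <- denormalize(yhat_norm, model$norm_y)
  metrics_target <- evaluate_metrics(rte$y, yhat_log)
  per_temp <- table(train = NULL)
  report <- list(
    seed = config$seed,
    counts = list(
      raw = nrow(raw), augmented = nrow(aug),
      train = nrow(sp$train), test = nrow(sp$test),
      train_per_temperature = as.list(table(sp$train$temperature_nominal)),
      test_per_temperature = as.list(table(sp$test$temperature_nominal))),
    reference_model = ref_model$meta,
    concentration_model = model$meta,
    calibration_voltage_mv = cal_v,
    metrics = list(
      normalized = unclass(metrics_norm)[c("mse", "mae", "var_y", "r_squared", "n")],
      normalized_percent = list(mse = 100 * metrics_norm$mse,
                                mae = 100 * metrics_norm$mae),
      log10_molar = unclass(metrics_target)[c("mse", "mae", "var_y", "r_squared", "n")]))
  res <- structure(list(config = config, raw = raw, train = sp$train,
                        test = sp$test, reference_model = ref_model,
                        concentration_model = model,
                        calibration = calibration, report = report),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sensor_log(raw, file.path(out_dir, "sensor_log_raw.csv"))
    save_model(model, file.path(out_dir, "concentration_model.json"))
    save_model(ref_model, file.path(out_dir, "reference_model.json"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("enzyme-ISFET pipeline (seed", r$seed, ")\n")
  cat(sprintf("  rows: %d raw -> %d augmented -> %d train / %d test\n",
              r$counts$raw, r$counts$augmented, r$counts$train, r$counts$test))
  cat(sprintf("  test metrics (normalized): MSE %.4g, MAE %.4g, R^2 %.5g\n",
              r$metrics$normalized$mse, r$metrics$normalized$mae,
              r$metrics$normalized$r_squared))
  cat(sprintf("  calibration voltage: %+.4g mV\n", r$calibration_voltage_mv))
  invisible(x)
}

#' Predict a carbaryl concentration from one or more readings
#'
#' The deployment path: the raw signal is compensated (per-sensor
#' calibration voltage and matrix correction, when a calibration state is
#' supplied), features are normalized with the model's stored training
#' ranges, fed forward, denormalized, and back-transformed to molarity.
#'
#' @param delta_vgs raw signal response(s), mV.
#' @param temperature solution temperature(s), degC. Temperatures outside
#'   the modeled 20-35 degC range are warned about and processed anyway.
#' @param model the concentration `isfet_model`.
#' @param calibration optional [calibration_state()]; omit for an
#'   uncompensated (population-reference) prediction.
#' @return Predicted concentration(s), molar (always > 0 for the log10
#'   transform).
#' @export
predict_concentration <- function(delta_vgs, temperature, model,
                                  calibration = NULL) {
  stopifnot(inherits(model, "isfet_model"))
  if (any(temperature < 20 | temperature > 35))
    warning("temperature outside the modeled 20-35 degC range", call. = FALSE)
  if (!is.null(calibration))
    delta_vgs <- compensate_signal(delta_vgs, calibration)
  n <- max(length(delta_vgs), length(temperature))
  x <- cbind(delta_vgs_mv = rep_len(delta_vgs, n),
             temperature_c = rep_len(temperature, n))
  predict(model, x)
}
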