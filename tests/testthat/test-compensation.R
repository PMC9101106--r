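test_that("the reference model recovers a noise-free constant exactly", {
  p0 <- noise_free_params(ref_temp_coeff = 0)
  blanks <- generate_blanks(replicates = 10L, params = p0, seed = 1L)
  m <- fit_reference_model(blanks,
                           train_config(max_epochs = 200L,
                                        mse_stop_threshold = 0.01, seed = 1L))
  # degenerate (constant) target passes through normalization untouched
  for (temp in c(20, 23.5, 27, 35))
    expect_equal(predict_reference(m, temp), 45.35, tolerance = 0.5)
})

test_that("the reference model tracks stratum means of noisy blanks", {
  p <- sim_params()
  blanks <- awgn_augment(generate_blanks(replicates = 25L, params = p,
                                         seed = 2L),
                         factor = 4L, seed = 3L)
  m <- fit_reference_model(blanks, train_config(max_epochs = 1500L,
                                                mse_stop_threshold = 0.01,
                                                seed = 2L))
  for (temp in c(20, 25, 30, 35)) {
    sel <- blanks$temperature_nominal == temp
    stratum_mean <- mean(blanks$delta_vgs_mv[sel])
    sem <- sd(blanks$delta_vgs_mv[sel]) / sqrt(sum(sel))
    # regression through the stratum means, allowing for fit bias at the
    # edges of the temperature range
    expect_equal(predict_reference(m, temp), stratum_mean,
                 tolerance = max(4 * sem, 0.02) / stratum_mean)
  }
})

test_that("reference fitting rejects degenerate inputs", {
  p <- sim_params(seed = 1L)
  expect_error(fit_reference_model(generate_blanks(25, 20L, p)),
               "single temperature")
  expect_error(fit_reference_model(generate_dataset(params = p)),
               "no-pesticide")
})

test_that("calibration voltage is the offset against the model prediction", {
  p0 <- noise_free_params(ref_temp_coeff = 0)
  blanks <- generate_blanks(replicates = 10L, params = p0, seed = 4L)
  m <- fit_reference_model(blanks, train_config(max_epochs = 200L,
                                                mse_stop_threshold = 0.01,
                                                seed = 4L))
  pred <- predict_reference(m, 25)
  expect_equal(calibration_voltage(pred, 25, m), 0)
  expect_equal(calibration_voltage(pred + 1.65, 25, m), 1.65,
               tolerance = 1e-10)
  # antisymmetry of the offset
  expect_equal(calibration_voltage(pred - 0.7, 25, m), -0.7,
               tolerance = 1e-10)
  # triplicate averaging
  expect_equal(calibration_voltage(pred + c(1, 2, 3), 25, m), 2,
               tolerance = 1e-10)
})

test_that("signal compensation subtracts the offset and adds the matrix term", {
  p0 <- noise_free_params(ref_temp_coeff = 0)
  blanks <- generate_blanks(replicates = 10L, params = p0, seed = 5L)
  m <- fit_reference_model(blanks, train_config(max_epochs = 100L,
                                                mse_stop_threshold = 0.01,
                                                seed = 5L))
  identity_state <- calibration_state(m, 0)
  expect_equal(compensate_signal(c(10, 20, 30), identity_state), c(10, 20, 30))
  st <- calibration_state(m, 1.5,
                          matrix_correction_from_inhibition_gap(2.68))
  expect_equal(compensate_signal(30, st), 30 - 1.5 - 1.206)
  expect_error(calibration_state(m, 0, matrix_correction = -1), ">= 0")
})

test_that("the published inhibition gaps map to the published corrections", {
  expect_equal(matrix_correction_from_inhibition_gap(2.68), 1.206)
  expect_equal(matrix_correction_from_inhibition_gap(3.24), 1.458)
  expect_equal(matrix_correction_from_inhibition_gap(0), 0)
  expect_error(matrix_correction_from_inhibition_gap(-0.1), ">= 0")
})

test_that("the mV-per-percent factor is the reference mean over 100", {
  p <- sim_params()
  expect_equal(p$mv_per_percent, p$ref_mean_25c / 100, tolerance = 0.02)
})

test_that("a saved reference model reproduces predictions exactly", {
  p <- sim_params()
  blanks <- generate_blanks(replicates = 10L, params = p, seed = 6L)
  m <- fit_reference_model(blanks, train_config(max_epochs = 100L,
                                                mse_stop_threshold = 0.01,
                                                seed = 6L))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  temps <- seq(20, 35, by = 2.5)
  expect_identical(predict_reference(m, temps), predict_reference(m2, temps))
})
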