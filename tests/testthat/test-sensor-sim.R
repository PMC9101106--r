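test_that("simulator parameters validate and carry the printed calibration", {
  p <- sim_params()
  expect_equal(p$ph_slope, 49.86)
  expect_equal(p$ph_intercept, 418.98)
  expect_equal(p$ref_mean_25c, 45.35)
  expect_equal(p$ref_sd, 1.6)
  expect_equal(p$inhib_slope, 6.6098)
  expect_equal(p$inhib_intercept, 134.62)
  expect_equal(p$matrix_offset_range, c(2.68, 3.24))
  expect_equal(p$mv_per_percent, 0.45)
  expect_error(sim_params(ref_sd = -1), "standard deviations")
  expect_error(sim_params(matrix_offset_range = c(3, 2)), "ordered")
  expect_warning(sim_params(ph_slope = 60), "45-55")
  expect_identical(sim_params_from_list(sim_params_to_list(p))[-13], p[-13])
})

test_that("pH response evaluates the calibration line deterministically", {
  p <- sim_params()
  expect_equal(ph_response(0, p), 418.98)
  expect_equal(ph_response(7, p), 768.00)
  expect_equal(ph_response(10, p) - ph_response(4, p), 299.16)
  expect_error(ph_response(-0.5, p), "pH")
  expect_error(ph_response(14.2, p), "pH")
})

test_that("reference signal is the mean when spread is zero and drifts with T", {
  p0 <- noise_free_params()
  expect_equal(reference_signal(25, p0), 45.35)
  expect_equal(reference_signal(25, noise_free_params(ref_temp_coeff = 2)), 45.35)
  expect_equal(reference_signal(30, noise_free_params(ref_temp_coeff = 0.3)),
               45.35 + 0.3 * 5)
  expect_error(reference_signal(Inf, p0))
})

test_that("sampled 25 degC reference signals are centred on the printed mean", {
  p <- sim_params()
  n <- 2000L
  draws <- withr::with_seed(11L, reference_signal(25, p, n = n))
  expect_lt(abs(mean(draws) - 45.35), 3 * p$ref_sd / sqrt(n))
  expect_lt(abs(sd(draws) - p$ref_sd), 0.15)
})

test_that("inhibition follows the ln-concentration line with clamping", {
  p <- sim_params()
  expect_equal(inhibition_from_concentration(1e-5, 25, p), 58.5218652616,
               tolerance = 1e-10)
  expect_equal(inhibition_from_concentration(1e-4, 25, p), 73.7414922093,
               tolerance = 1e-10)
  expect_equal(inhibition_from_concentration(1, 25, p), 100)   # clamp high
  expect_equal(inhibition_from_concentration(1e-12, 25, p), 0) # clamp low
  # temperature adjustment is linear about 25 degC
  expect_equal(inhibition_from_concentration(1e-5, 30, p) -
                 inhibition_from_concentration(1e-5, 25, p),
               5 * p$inhib_temp_coeff)
  expect_error(inhibition_from_concentration(0, 25, p), "> 0")
  expect_error(inhibition_from_concentration(-1e-6, 25, p), "> 0")
})

test_that("carbaryl signal inverts the inhibition readout", {
  p0 <- noise_free_params()
  # zero inhibition leaves the reference signal untouched
  expect_equal(carbaryl_signal(1e-12, 25, "buffer", p0), 45.35)
  # the printed minimum carbaryl signal: 36.54 % inhibition off a 45.35 mV
  # reference gives 28.78 mV
  c_star <- exp((36.54 - p0$inhib_intercept) / p0$inhib_slope)
  expect_equal(carbaryl_signal(c_star, 25, "buffer", p0), 28.77911,
               tolerance = 1e-5)
  expect_error(carbaryl_signal(-1, 25, "buffer", p0), "> 0")
})

test_that("noise-free signal strictly decreases with concentration", {
  p0 <- noise_free_params()
  conc <- 10^seq(-6, -4, length.out = 25)
  for (temp in c(20, 25, 30, 35)) {
    sig <- carbaryl_signal(conc, temp, "buffer", p0)
    expect_true(all(diff(sig) < 0))
  }
})

test_that("inhibition round-trips through the signal inversion", {
  p0 <- noise_free_params()
  ref <- expected_reference(25, p0)
  for (conc in 10^seq(-6.5, -3.5, by = 0.5)) {
    sig <- carbaryl_signal(conc, 25, "buffer", p0)
    expect_equal(percent_inhibition(ref, sig),
                 inhibition_from_concentration(conc, 25, p0),
                 tolerance = 1e-9)
  }
})

test_that("extract matrix offsets raise the signal by the inhibition gap", {
  # pin the offset range to a point so the draw is deterministic in value
  p0 <- noise_free_params(matrix_offset_range = c(2.68, 2.68))
  buffer <- carbaryl_signal(1e-5, 25, "buffer", p0)
  extract <- withr::with_seed(3L, carbaryl_signal(1e-5, 25, "extract", p0))
  gap_mv <- extract - buffer
  expect_equal(gap_mv, 45.35 * 2.68 / 100, tolerance = 1e-10)
  # and that is the 0.45 mV/percent equivalence to within 1 percent
  expect_equal(gap_mv, matrix_correction_from_inhibition_gap(2.68),
               tolerance = 0.01)
})

test_that("the factorial generator has the right size and is reproducible", {
  p <- sim_params(seed = 42L)
  d <- generate_dataset(params = p)
  expect_equal(nrow(d), 200L)  # 5 x 4 x 10
  expect_equal(nrow(generate_dataset(1e-5, 25, 1L, params = p)), 1L)
  expect_setequal(unique(d$concentration_m), 10^(-7:-3))
  expect_setequal(unique(d$temperature_nominal), c(20, 25, 30, 35))
  expect_identical(d, generate_dataset(params = p))
  expect_error(generate_dataset(numeric(0), params = p), "non-empty")
  expect_error(generate_dataset(replicates = 0, params = p), ">= 1")
  # blanks carry NA concentrations and respect the design size
  b <- generate_blanks(params = p)
  expect_equal(nrow(b), 40L)
  expect_true(all(is.na(b$concentration_m)))
})

test_that("sensor logs survive the CSV round trip", {
  p <- sim_params(seed = 5L)
  d <- rbind(generate_dataset(params = p, replicates = 2L),
             generate_blanks(params = p, replicates = 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sensor_log(d, path)
  header <- readLines(path, n = 1L)
  expect_identical(header,
                   "delta_vgs_mv,temperature_c,matrix,concentration_m,replicate")
  back <- read_sensor_log(path)
  expect_equal(back$delta_vgs_mv, d$delta_vgs_mv, tolerance = 1e-12)
  expect_equal(back$concentration_m, d$concentration_m)
  expect_equal(back$matrix, d$matrix)
})
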