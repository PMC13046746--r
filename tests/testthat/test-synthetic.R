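test_that("generators are pure functions of their spec (seed included)", {
  expect_identical(gen_drift_log(drift_sim_spec(seed = 3)),
                   gen_drift_log(drift_sim_spec(seed = 3)))
  expect_false(identical(gen_drift_log(drift_sim_spec(seed = 3)),
                         gen_drift_log(drift_sim_spec(seed = 4))))
  expect_identical(gen_icp(icp_sim_spec(seed = 3))$samples,
                   gen_icp(icp_sim_spec(seed = 3))$samples)
  expect_identical(gen_accuracy_grid(error_model = uniform_error_model(),
                                     seed = 3),
                   gen_accuracy_grid(error_model = uniform_error_model(),
                                     seed = 3))
})

test_that("generators do not disturb the global RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(gen_drift_log(drift_sim_spec(n_implants = 1, duration_weeks = 1)))
  invisible(gen_icp(icp_sim_spec()))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("drift log has one record per implant per day", {
  log <- gen_drift_log(drift_sim_spec())
  expect_equal(nrow(log), 16 * 52 * 7)
  expect_equal(length(unique(log$implant_id)), 16)
  expect_true(all(table(log$implant_id) == 364))
  expect_true(inherits(log$timestamp, "POSIXct"))
  # shared barometer: identical walk across implants, within bounds
  b1 <- log$barometer[log$implant_id == "implant_01"]
  b2 <- log$barometer[log$implant_id == "implant_16"]
  expect_identical(b1, b2)
  expect_true(all(b1 >= 730 & b1 <= 790))
})

test_that("noiseless drift log reproduces the injected rate exactly", {
  spec <- drift_sim_spec(n_implants = 1, duration_weeks = 52,
                         true_drift_rate = 1.5, noise_sd = 0, seed = 2)
  s <- zero_point_series(gen_drift_log(spec), "implant_01")
  f <- drift_rate_fit(s)
  expect_equal(f$rate_mmhg_per_year, 1.5, tolerance = 1e-9)
  expect_lt(f$se, 1e-9)
})

test_that("standard ICP read is 504 samples of 10.08 s at 50 Hz", {
  rec <- gen_icp(icp_sim_spec())
  expect_length(rec$samples, 504)
  expect_equal(rec$fs, 50)
  expect_equal(max(rec$t_s), 503 / 50)
})

test_that("noiseless cardiac amplitude is exactly peak-to-trough pulse_amp", {
  rec <- gen_icp(icp_sim_spec(duration_s = 60, pulse_amp = 2.4, resp_amp = 0,
                              noise_sd = 0))
  expect_equal(max(rec$samples) - min(rec$samples), 2.4, tolerance = 1e-3)
  expect_equal(mean(rec$samples), 10, tolerance = 1e-3)
})

test_that("posture schedule applies additive step offsets", {
  sched <- data.frame(start_s = c(0, 5), posture = c("lying", "standing"),
                      offset_mmhg = c(5, -10))
  rec <- gen_icp(icp_sim_spec(duration_s = 10, pulse_amp = 0, resp_amp = 0,
                              noise_sd = 0, posture_schedule = sched))
  expect_equal(unique(rec$samples[rec$t_s < 5]), 15)
  expect_equal(unique(rec$samples[rec$t_s >= 5]), 0)
  expect_equal(unique(rec$posture[rec$t_s < 5]), "lying")
  expect_equal(unique(rec$posture[rec$t_s >= 5]), "standing")
})

test_that("accuracy grid is a full factorial spanning the exact ranges", {
  grid <- gen_accuracy_grid()
  expect_equal(nrow(grid), 42 * 11)
  expect_equal(range(grid$set_pressure), c(475, 950))
  expect_equal(range(grid$set_temp), c(35, 45))
  expect_equal(nrow(unique(grid[, c("set_pressure", "set_temp")])), 42 * 11)
  # zero error model: readings equal set points
  expect_equal(grid$pressure_reading, grid$set_pressure)
  expect_equal(grid$temp_reading, grid$set_temp)
})

test_that("uniform error model stays within its half-widths", {
  grid <- gen_accuracy_grid(error_model = uniform_error_model(1.5, 0.5),
                            seed = 77)
  expect_true(all(abs(grid$pressure_reading - grid$set_pressure) <= 1.5))
  expect_true(all(abs(grid$temp_reading - grid$set_temp) <= 0.5))
  expect_gt(sd(grid$pressure_reading - grid$set_pressure), 0)
})

test_that("spec constructors validate their inputs", {
  expect_error(drift_sim_spec(duration_weeks = 0), "duration_weeks")
  expect_error(drift_sim_spec(noise_sd = -1), "noise_sd")
  expect_error(icp_sim_spec(duration_s = -1), "duration_s")
  expect_error(icp_sim_spec(pulse_amp = -1), "pulse_amp")
  expect_error(gen_accuracy_grid(n_pressure = 1), ">= 2")
  expect_error(gen_accuracy_grid(pressure_range = c(950, 475)), "ordered")
})
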