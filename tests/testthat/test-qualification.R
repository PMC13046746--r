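test_that("default acceleration factor is 23.4 to one decimal", {
  af <- acceleration_factor(aging_protocol())
  expect_equal(af, 2^4.6 * 162 / 168, tolerance = 1e-14)
  expect_equal(round(af, 1), 23.4)
})

test_that("acceleration factor identities hold", {
  # equal temperatures and full duty -> no acceleration
  expect_equal(acceleration_factor(aging_protocol(39, 39, 2, 1)), 1)
  # duty 1 removes the duty discount
  expect_equal(acceleration_factor(aging_protocol(duty = 1)), 2^4.6,
               tolerance = 1e-14)
  # AF is monotone in the elevated temperature and in q10
  afs <- vapply(c(60, 70, 85, 95),
                function(te) acceleration_factor(aging_protocol(39, te)),
                numeric(1))
  expect_true(all(diff(afs) > 0))
  expect_gt(acceleration_factor(aging_protocol(q10 = 2.2)),
            acceleration_factor(aging_protocol(q10 = 2)))
})

test_that("22 accelerated weeks map to about 10 years", {
  yrs <- equivalent_duration(22)
  expect_equal(yrs, 22 * (2^4.6 * 162 / 168) * 7 / 365.25, tolerance = 1e-14)
  expect_equal(round(yrs), 10)
})

test_that("equivalent_duration and required_test_weeks are inverse", {
  set.seed(41)
  for (w in runif(10, 1, 100)) {
    expect_equal(required_test_weeks(equivalent_duration(w)), w,
                 tolerance = 1e-12)
  }
  # trivial protocol: weeks in = weeks out
  p1 <- aging_protocol(39, 39, 2, 1)
  expect_equal(equivalent_duration(52.178571, p1) , 52.178571 * 7 / 365.25,
               tolerance = 1e-9)
})

test_that("aging_protocol validates inputs", {
  expect_error(aging_protocol(q10 = 1), "q10")
  expect_error(aging_protocol(duty = 0), "duty")
  expect_error(aging_protocol(85, 39), "elevated_temp")
  expect_error(equivalent_duration(-1), "> 0")
})

test_that("zero-point arithmetic subtracts barometer and fluid head", {
  # 1 cm of fluid head is 0.73559 mmHg
  expect_equal(zero_point_error(760.73559, 760, head_cm = 1), 0,
               tolerance = 1e-12)
  expect_equal(zero_point_error(762, 760, head_cm = 0), 2)
  # a 0.36 cm column: 0.36 * 0.73559 = 0.2648124
  expect_equal(zero_point_error(760, 760, head_cm = 0.36), -0.2648124,
               tolerance = 1e-12)
  expect_error(zero_point_error(760), "barometer")
  expect_error(zero_point_error(760, NA), "barometer")
})

test_that("zero-point series is re-referenced to the first reading", {
  log <- gen_drift_log(drift_sim_spec(n_implants = 2, duration_weeks = 4,
                                      noise_sd = 0.3, seed = 5))
  s <- zero_point_series(log, "implant_01")
  expect_equal(s$zero_point[1], 0)
  expect_equal(s$t_days[1], 0)
  expect_true(all(diff(s$t_days) > 0))
  expect_error(zero_point_series(log, "implant_99"), "unknown implant_id")
})

test_that("zero-point error is invariant to the shared barometer walk", {
  # with zero noise and zero drift the zero-point error is exactly 0
  log <- gen_drift_log(drift_sim_spec(n_implants = 1, duration_weeks = 8,
                                      true_drift_rate = 0, noise_sd = 0,
                                      baro_walk_sd = 5, seed = 6))
  s <- zero_point_series(log, "implant_01")
  expect_equal(max(abs(s$zero_point)), 0, tolerance = 1e-12)
})

test_that("drift_qualify applies the excursion limit", {
  s <- data.frame(timestamp = as.POSIXct("2024-01-01", tz = "UTC") + 0:9,
                  zero_point = c(0, 0.5, -1.9, 0.3, rep(0, 6)))
  q <- drift_qualify(s, limit_mmhg = 2)
  expect_true(q$pass)
  expect_equal(q$max_excursion_mmhg, 1.9)
  s$zero_point[5] <- -2.4
  q2 <- drift_qualify(s, limit_mmhg = 2)
  expect_false(q2$pass)
  expect_equal(q2$at, s$timestamp[5])
  expect_error(drift_qualify(s[0, ]), "empty")
})

test_that("drift_rate_fit recovers an injected drift within 3 SE", {
  spec <- drift_sim_spec(n_implants = 1, duration_weeks = 52,
                         true_drift_rate = 0.8, noise_sd = 0.2, seed = 7)
  s <- zero_point_series(gen_drift_log(spec), "implant_01")
  f <- drift_rate_fit(s)
  expect_lt(abs(f$rate_mmhg_per_year - 0.8), 3 * f$se)
  expect_error(drift_rate_fit(s[1:2, ]), "at least 3")
})

test_that("a 16-implant cohort with zero true drift passes the 2 mmHg limit", {
  log <- gen_drift_log(drift_sim_spec(seed = 8))
  ids <- unique(log$implant_id)
  expect_length(ids, 16)
  for (id in ids) {
    q <- drift_qualify(zero_point_series(log, id), limit_mmhg = 2)
    expect_true(q$pass)
  }
})

test_that("drift rate recovery succeeds in at least 95% of 100 replicates", {
  hits <- 0L
  for (seed in 1:100) {
    spec <- drift_sim_spec(n_implants = 1, duration_weeks = 52,
                           true_drift_rate = 0.5, noise_sd = 0.2, seed = seed)
    s <- zero_point_series(gen_drift_log(spec), "implant_01")
    f <- drift_rate_fit(s)
    if (abs(f$rate_mmhg_per_year - 0.5) < 3 * f$se) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("accuracy evaluation passes a perfect grid and spans the ranges", {
  grid <- gen_accuracy_grid()
  expect_equal(nrow(grid), 42 * 11)
  res <- accuracy_evaluate(grid)
  expect_true(res$pass)
  expect_true(res$coverage_ok)
  expect_equal(res$summary$mean_error, c(0, 0))
  expect_length(res$failed_cells, 0)
})

test_that("uniform(-1, 1) errors always pass the 2 mmHg / 2 degC tolerance", {
  for (seed in 1:5) {
    grid <- gen_accuracy_grid(error_model = uniform_error_model(1, 1),
                              seed = seed)
    expect_true(accuracy_evaluate(grid)$pass)
  }
})

test_that("one injected out-of-tolerance cell fails exactly that cell", {
  grid <- gen_accuracy_grid()
  grid$pressure_reading[100] <- grid$set_pressure[100] + 2.5
  res <- accuracy_evaluate(grid)
  expect_false(res$pass)
  expect_true(res$coverage_ok)
  expect_equal(res$failed_cells, 100)
})

test_that("a grid not spanning the ranges is a coverage failure, not tolerance", {
  grid <- gen_accuracy_grid(pressure_range = c(500, 900))
  res <- accuracy_evaluate(grid)
  expect_false(res$coverage_ok)
  expect_false(res$pass)
  expect_length(res$failed_cells, 0)   # every cell is within tolerance
  expect_error(accuracy_evaluate(grid[, 1:3]), "missing column")
})

test_that("tolerance_spec validates inputs", {
  expect_error(tolerance_spec(pressure_tol = 0), "tolerances")
  expect_error(tolerance_spec(pressure_range = c(950, 475)), "ordered")
})
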