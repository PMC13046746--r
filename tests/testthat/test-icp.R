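pure_spec <- function(...) {
  icp_sim_spec(duration_s = 30, resp_amp = 0, noise_sd = 0, ...)
}

test_that("pure sinusoid recovers mean, amplitude and heart rate", {
  rec <- gen_icp(pure_spec(mean_icp = 10, pulse_amp = 2, heart_rate = 72))
  pm <- pulse_metrics(rec)
  expect_equal(pm$mean_icp, 10, tolerance = 1e-6)
  expect_equal(pm$pulse_amplitude, 2, tolerance = 0.02 * 2)
  expect_equal(pm$heart_rate_est, 72, tolerance = 1)
  expect_equal(pm$quality_flag, "ok")
})

test_that("heart rate is recovered within 1 bpm across the clinical range", {
  for (hr in c(50, 70, 90, 110)) {
    rec <- gen_icp(pure_spec(heart_rate = hr))
    pm <- pulse_metrics(rec)
    expect_equal(pm$heart_rate_est, hr, tolerance = 1)
  }
})

test_that("amplitude and HR are recovered at noise sd 0.2 on standard reads", {
  rec <- gen_icp(icp_sim_spec(noise_sd = 0.2, seed = 12))
  pm <- pulse_metrics(rec)
  expect_equal(pm$pulse_amplitude, 2, tolerance = 0.1 * 2)
  expect_equal(pm$heart_rate_est, 70, tolerance = 1)
})

test_that("spectral mode agrees with beat mode on a pure sinusoid", {
  rec <- gen_icp(pure_spec(pulse_amp = 3, heart_rate = 60))
  beat <- pulse_metrics(rec, mode = "beat")$pulse_amplitude
  spec <- pulse_metrics(rec, mode = "spectral")$pulse_amplitude
  expect_equal(beat, 3, tolerance = 0.06)
  expect_equal(spec, 3, tolerance = 0.06)
})

test_that("amplitude is offset-invariant and scales linearly", {
  rec <- gen_icp(icp_sim_spec(noise_sd = 0.1, seed = 13))
  pm <- pulse_metrics(rec)
  shifted <- rec; shifted$samples <- rec$samples + 25
  pm_s <- pulse_metrics(shifted)
  expect_equal(pm_s$pulse_amplitude, pm$pulse_amplitude, tolerance = 1e-9)
  expect_equal(pm_s$mean_icp, pm$mean_icp + 25, tolerance = 1e-9)
  scaled <- rec; scaled$samples <- rec$samples * 2
  expect_equal(pulse_metrics(scaled)$pulse_amplitude, 2 * pm$pulse_amplitude,
               tolerance = 1e-9)
})

test_that("a flat recording reports zero amplitude and low_beats", {
  rec <- gen_icp(icp_sim_spec(pulse_amp = 0, resp_amp = 0, noise_sd = 0))
  pm <- pulse_metrics(rec)
  expect_equal(pm$pulse_amplitude, 0)
  expect_equal(pm$n_beats, 0L)
  expect_equal(pm$quality_flag, "low_beats")
  expect_true(is.na(pm$heart_rate_est))
})

test_that("negative mean ICP (upright posture) is handled, not clipped", {
  rec <- gen_icp(pure_spec(mean_icp = -8))
  pm <- pulse_metrics(rec)
  expect_equal(pm$mean_icp, -8, tolerance = 1e-6)
  expect_equal(pm$pulse_amplitude, 2, tolerance = 0.05)
})

test_that("the generator refuses cardiac frequencies at or above Nyquist", {
  expect_error(icp_sim_spec(fs = 4, heart_rate = 120), "Nyquist")
  expect_silent(icp_sim_spec(fs = 50, heart_rate = 110))
})

test_that("pulse_metrics validates the recording and band", {
  rec <- gen_icp(icp_sim_spec(duration_s = 3))
  expect_error(pulse_metrics(rec), "shorter than 5 s")
  rec10 <- gen_icp(icp_sim_spec())
  expect_error(pulse_metrics(rec10, band = c(3, 0.67)), "band")
  expect_error(pulse_metrics(rec10, band = c(0.67, 30)), "band")
  expect_error(pulse_metrics(list(samples = NULL, fs = 50)), "samples")
})

test_that("reading_summary reports the majority posture", {
  sched <- data.frame(start_s = c(0, 8), posture = c("lying", "standing"),
                      offset_mmhg = c(0, -10))
  rec <- gen_icp(icp_sim_spec(duration_s = 10.08, posture_schedule = sched,
                              noise_sd = 0))
  row <- reading_summary(rec)
  expect_equal(row$posture, "lying")     # 8 s lying vs 2.08 s standing
  rec2 <- gen_icp(icp_sim_spec(noise_sd = 0))
  expect_equal(reading_summary(rec2)$posture, "unspecified")
})

make_diary <- function(n = 60, span_days = 180, postures = c("lying", "standing"),
                       means = c(12, -8), amp = 2, seed0 = 100,
                       bump = NULL) {
  t0 <- as.POSIXct("2024-01-01 08:00:00", tz = "UTC")
  rows <- lapply(seq_len(n), function(i) {
    k <- ((i - 1) %% length(postures)) + 1
    mu <- means[k] + if (!is.null(bump) && i == bump$i) bump$delta else 0
    rec <- gen_icp(icp_sim_spec(mean_icp = mu, pulse_amp = amp,
                                noise_sd = 0.2, seed = seed0 + i),
                   start_time = t0 + (i - 1) / n * span_days * 86400)
    rec$posture <- rep(postures[k], length(rec$samples))
    reading_summary(rec)
  })
  do.call(rbind, rows)
}

test_that("longitudinal summary separates posture medians", {
  rows <- make_diary()
  ls <- longitudinal_summary(rows, window_days = 30)
  expect_true(all(c("lying", "standing") %in% rows$posture))
  med <- tapply(rows$mean_icp, rows$posture, median)
  expect_equal(unname(med["lying"] - med["standing"]), 20, tolerance = 0.5)
  expect_true(all(ls$windows$n >= 1))
  # stable generator -> window medians stay near the global median
  expect_true(all(ls$stability < 1))
  expect_error(longitudinal_summary(rows[0, ]), "no diary rows")
})

flat_rows <- function(n = 60, span_days = 120, mean_icp = 10,
                      posture = "lying") {
  data.frame(
    timestamp = as.POSIXct("2024-01-01", tz = "UTC") +
      seq(0, span_days, length.out = n) * 86400,
    patient_id = "p", posture = posture,
    mean_icp = mean_icp, pulse_amplitude = 2, heart_rate_est = 70,
    quality_flag = "ok", stringsAsFactors = FALSE)
}

test_that("a constant diary produces no excursion flags", {
  rows <- flat_rows()
  fl <- excursion_flags(rows, baseline_window_days = 30, k = 3)
  expect_false(any(fl$status == "flagged"))
  # early readings lack a baseline
  expect_true(any(fl$status == "not_evaluable"))
  expect_error(excursion_flags(rows, baseline_window_days = 1000),
               "shorter than the diary span")
})

test_that("a +15 mmHg step change flags every evaluable post-step reading", {
  rows <- flat_rows(n = 60, span_days = 120)
  post <- rows$timestamp >= rows$timestamp[1] + 96 * 86400 # last 20%
  rows$mean_icp[post] <- rows$mean_icp[post] + 15
  fl <- excursion_flags(rows, baseline_window_days = 110, k = 3)
  expect_true(all(fl$status[post] == "flagged"))
  expect_false(any(fl$status[!post] == "flagged"))
})

test_that("k large enough suppresses all flags on a noisy diary", {
  rows <- make_diary(n = 40, span_days = 80, postures = "lying", means = 10)
  fl <- excursion_flags(rows, baseline_window_days = 30, k = 1e12)
  expect_false(any(fl$status == "flagged"))
})

test_that("excursion baseline is posture-matched", {
  # a standing reading at lying-level ICP must be flagged against the
  # standing baseline even though it is typical of the lying group
  lying <- flat_rows(n = 40, span_days = 120, mean_icp = 12,
                     posture = "lying")
  standing <- flat_rows(n = 40, span_days = 120, mean_icp = -8,
                        posture = "standing")
  standing$timestamp <- standing$timestamp + 43200
  rows <- rbind(lying, standing)
  i_target <- which(rows$posture == "standing")[35]
  rows$mean_icp[i_target] <- 12
  fl <- excursion_flags(rows, baseline_window_days = 60, k = 3)
  expect_equal(fl$status[fl$mean_icp == 12 & fl$posture == "standing"],
               "flagged")
  expect_false(any(fl$status[fl$posture == "lying"] == "flagged"))
})
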