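# Seeded generators for every input the pipeline consumes: drift-rig logs,
# accuracy grids and ICP recordings (head meshes live in mesh.R). Each
# generator is a pure function of its spec, including the seed; the global
# RNG stream is saved and restored around every draw.

with_seed <- function(seed, expr) {
  old <- .Random.seed_exists()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Drift-rig simulation spec
#'
#' Emulates the zero-point drift rig: implants immersed under a fixed fluid
#' head at body-like temperature, read at a fixed cadence against a shared
#' calibrated barometer that wanders as a bounded random walk.
#'
#' @param n_implants number of implants on the rig (default 16).
#' @param duration_weeks test duration (default 52).
#' @param read_interval days between readings (default 1).
#' @param true_drift_rate injected sensor drift, mmHg/year.
#' @param noise_sd per-reading noise SD, mmHg.
#' @param head_height_cm fluid column above the implants, cm (default 1).
#' @param baro_mean initial barometer level, mmHg (default 760).
#' @param baro_walk_sd daily barometer random-walk SD, mmHg (clipped to
#'   730-790 mmHg).
#' @param rig_temp rig temperature, degC (default 38).
#' @param seed integer RNG seed (required; no global state).
#' @return object of class `drift_sim_spec`.
#' @export
drift_sim_spec <- function(n_implants = 16, duration_weeks = 52,
                           read_interval = 1, true_drift_rate = 0,
                           noise_sd = 0.2, head_height_cm = 1,
                           baro_mean = 760, baro_walk_sd = 2,
                           rig_temp = 38, seed = 1) {
  if (duration_weeks <= 0) stop("duration_weeks must be > 0")
  if (read_interval <= 0) stop("read_interval must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_implants < 1) stop("n_implants must be >= 1")
  structure(as.list(environment()), class = "drift_sim_spec")
}

#' Generate a synthetic drift-rig log
#'
#' One record per implant per read interval. The implant absolute pressure is
#' barometer + fluid head + injected drift + noise, so the zero-point error
#' recovers exactly the injected drift plus noise.
#'
#' @param spec a [drift_sim_spec()].
#' @return data frame (`DriftLog` schema): `timestamp` (POSIXct UTC),
#'   `implant_id`, `implant_abs_pressure`, `barometer`, `head_cm`,
#'   `temperature`.
#' @export
gen_drift_log <- function(spec = drift_sim_spec()) {
  stopifnot(inherits(spec, "drift_sim_spec"))
  t_days <- seq(0, spec$duration_weeks * 7 - 1e-9, by = spec$read_interval)
  n_t <- length(t_days)
  with_seed(spec$seed, {
    # shared barometer: bounded Gaussian random walk, one step per reading
    steps <- stats::rnorm(n_t, 0, spec$baro_walk_sd * sqrt(spec$read_interval))
    steps[1] <- 0
    baro <- spec$baro_mean + cumsum(steps)
    baro <- pmin(790, pmax(730, baro))
    start <- as.POSIXct("2024-01-01 09:00:00", tz = "UTC")
    out <- do.call(rbind, lapply(seq_len(spec$n_implants), function(id) {
      drift <- spec$true_drift_rate * t_days / 365.25
      noise <- if (spec$noise_sd > 0) stats::rnorm(n_t, 0, spec$noise_sd) else 0
      data.frame(
        timestamp = start + t_days * 86400,
        implant_id = sprintf("implant_%02d", id),
        implant_abs_pressure = baro + spec$head_height_cm * CM_FLUID_TO_MMHG +
          drift + noise,
        barometer = baro,
        head_cm = spec$head_height_cm,
        temperature = spec$rig_temp)
    }))
    rownames(out) <- NULL
    out
  })
}

#' ICP recording simulation spec
#'
#' Emulates a telemetric ICP read: a mean level plus a cardiac pulse wave,
#' a respiratory component, white noise, and additive posture offsets on a
#' schedule. The cardiac component is a sinusoid (two optional harmonics,
#' off by default) whose peak-to-trough amplitude is `pulse_amp` exactly
#' when harmonics, respiration and noise are zero.
#'
#' @param duration_s recording length, seconds (default 10.08 = 504 samples
#'   at 50 Hz, the standard read).
#' @param fs sampling rate, Hz (default 50). Must exceed twice the cardiac
#'   frequency.
#' @param mean_icp mean ICP, mmHg (may be negative when upright).
#' @param pulse_amp cardiac peak-to-trough amplitude, mmHg (default 2;
#'   asymptomatic medians run 1-3 mmHg).
#' @param heart_rate beats/min (default 70).
#' @param resp_amp respiratory peak-to-trough amplitude, mmHg.
#' @param resp_rate breaths/min (default 15).
#' @param noise_sd white-noise SD, mmHg.
#' @param harmonics length-2 relative amplitudes of the 2nd and 3rd cardiac
#'   harmonics (default both 0).
#' @param posture_schedule data frame `start_s`, `posture`, `offset_mmhg`;
#'   offsets are additive step changes. `NULL` for a single unspecified
#'   posture.
#' @param seed integer RNG seed.
#' @return object of class `icp_sim_spec`.
#' @export
icp_sim_spec <- function(duration_s = 10.08, fs = 50, mean_icp = 10,
                         pulse_amp = 2, heart_rate = 70, resp_amp = 0.5,
                         resp_rate = 15, noise_sd = 0.2,
                         harmonics = c(0, 0), posture_schedule = NULL,
                         seed = 1) {
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (pulse_amp < 0) stop("pulse_amp must be >= 0")
  if (fs <= 2 * heart_rate / 60)
    stop("Nyquist violation: fs must exceed twice the cardiac frequency (",
         round(heart_rate / 60, 2), " Hz)")
  structure(as.list(environment()), class = "icp_sim_spec")
}

#' Generate a synthetic ICP recording
#'
#' @param spec an [icp_sim_spec()].
#' @param start_time recording start (POSIXct, default a fixed UTC instant).
#' @param patient_id opaque identifier carried through to summaries.
#' @return object of class `icp_recording`: `samples` (mmHg), `fs`, `t_s`,
#'   `posture` (per-sample labels), `start_time`, `patient_id`, `spec`.
#' @export
gen_icp <- function(spec = icp_sim_spec(),
                    start_time = as.POSIXct("2024-01-01 08:00:00", tz = "UTC"),
                    patient_id = "synthetic") {
  stopifnot(inherits(spec, "icp_sim_spec"))
  n <- round(spec$duration_s * spec$fs)
  t <- (seq_len(n) - 1) / spec$fs
  fc <- spec$heart_rate / 60
  fr <- spec$resp_rate / 60
  cardiac <- (spec$pulse_amp / 2) * (
    sin(2 * pi * fc * t) +
      spec$harmonics[1] * sin(2 * pi * 2 * fc * t) +
      spec$harmonics[2] * sin(2 * pi * 3 * fc * t))
  resp <- (spec$resp_amp / 2) * sin(2 * pi * fr * t)
  posture <- rep("unspecified", n)
  offset <- numeric(n)
  if (!is.null(spec$posture_schedule)) {
    sched <- spec$posture_schedule[order(spec$posture_schedule$start_s), ]
    for (i in seq_len(nrow(sched))) {
      sel <- t >= sched$start_s[i]
      posture[sel] <- as.character(sched$posture[i])
      offset[sel] <- sched$offset_mmhg[i]
    }
  }
  noise <- if (spec$noise_sd > 0)
    with_seed(spec$seed, stats::rnorm(n, 0, spec$noise_sd)) else numeric(n)
  structure(list(samples = spec$mean_icp + offset + cardiac + resp + noise,
                 fs = spec$fs, t_s = t, posture = posture,
                 start_time = start_time, patient_id = patient_id,
                 spec = spec),
            class = "icp_recording")
}

#' @export
print.icp_recording <- function(x, ...) {
  cat(sprintf("icp_recording: %d samples at %g Hz (%.2f s), patient %s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$patient_id))
  invisible(x)
}

#' Generate a synthetic accuracy grid
#'
#' Full factorial set-point grid over the tested pressure and temperature
#' ranges, with readings perturbed by an injectable error model.
#'
#' @param pressure_range mmHg pair (default 475-950 absolute).
#' @param temp_range degC pair (default 35-45).
#' @param n_pressure,n_temp grid sizes (each >= 2).
#' @param error_model function `(set_pressure, set_temp)` returning a data
#'   frame/list with vectors `pressure_error` and `temp_error` (mmHg, degC);
#'   the default injects zero error.
#' @param seed integer RNG seed (set before calling `error_model`).
#' @return data frame: `set_pressure`, `set_temp`, `pressure_reading`,
#'   `temp_reading`.
#' @export
gen_accuracy_grid <- function(pressure_range = c(475, 950),
                              temp_range = c(35, 45),
                              n_pressure = 42, n_temp = 11,
                              error_model = zero_error_model,
                              seed = 1) {
  if (diff(pressure_range) <= 0 || diff(temp_range) <= 0)
    stop("ranges must be ordered (low, high)")
  if (n_pressure < 2 || n_temp < 2) stop("grid counts must be >= 2")
  g <- expand.grid(
    set_pressure = seq(pressure_range[1], pressure_range[2],
                       length.out = n_pressure),
    set_temp = seq(temp_range[1], temp_range[2], length.out = n_temp))
  err <- with_seed(seed, error_model(g$set_pressure, g$set_temp))
  data.frame(set_pressure = g$set_pressure, set_temp = g$set_temp,
             pressure_reading = g$set_pressure + err$pressure_error,
             temp_reading = g$set_temp + err$temp_error)
}

#' Error models for [gen_accuracy_grid()]
#'
#' `zero_error_model` returns exact readings; `uniform_error_model(p, t)`
#' builds a model with iid uniform(-p, p) mmHg and uniform(-t, t) degC
#' errors.
#'
#' @param set_pressure,set_temp set-point vectors (supplied by the grid
#'   generator).
#' @return data frame with `pressure_error`, `temp_error`.
#' @export
zero_error_model <- function(set_pressure, set_temp) {
  data.frame(pressure_error = numeric(length(set_pressure)),
             temp_error = numeric(length(set_temp)))
}

#' @rdname zero_error_model
#' @param p_max,t_max half-widths of the uniform error distributions.
#' @export
uniform_error_model <- function(p_max = 1, t_max = 1) {
  function(set_pressure, set_temp) {
    n <- length(set_pressure)
    data.frame(pressure_error = stats::runif(n, -p_max, p_max),
               temp_error = stats::runif(n, -t_max, t_max))
  }
}

#' Write a generator table as CSV (ISO-8601 timestamps)
#'
#' @param df data frame; POSIXct columns are serialized as ISO-8601 UTC.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  df2 <- df
  for (nm in names(df2)) {
    if (inherits(df2[[nm]], "POSIXct"))
      df2[[nm]] <- format(df2[[nm]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  utils::write.csv(df2, path, row.names = FALSE)
  invisible(path)
}

#' Read a CSV with a declared schema
#'
#' Checks required columns (errors name the missing ones) and parses
#' ISO-8601 timestamp columns back to POSIXct UTC.
#'
#' @param path CSV file.
#' @param required character vector of required column names.
#' @param timestamp_cols columns to parse as ISO-8601 timestamps.
#' @return data frame.
#' @export
read_table_csv <- function(path, required = character(),
                           timestamp_cols = intersect("timestamp", required)) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (nm in intersect(timestamp_cols, names(df))) {
    parsed <- as.POSIXct(df[[nm]], format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    bad <- which(is.na(parsed) & !is.na(df[[nm]]))
    if (length(bad))
      stop(path, ": column ", nm, " row ", bad[1], " is not ISO-8601")
    df[[nm]] <- parsed
  }
  df
}
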