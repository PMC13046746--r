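#' Conversion from cm of buffered-saline head to mmHg
#'
#' The drift and accuracy rigs keep implants under a fixed fluid column; its
#' hydrostatic contribution is 0.73559 mmHg per cm and is subtracted together
#' with the barometer reading. The constant is used verbatim, never
#' re-derived.
#' @export
CM_FLUID_TO_MMHG <- 0.73559

#' Accelerated-aging protocol (Q10 Arrhenius shortcut)
#'
#' Storage at an elevated temperature multiplies reaction rates by
#' `q10^(dT/10)` per the ASTM F1980 accelerated-aging convention; the duty
#' factor accounts for time spent back at working temperature for readings
#' (162 of 168 weekly hours at the elevated temperature by default).
#'
#' @param working_temp working (body/rig) temperature, degC (default 39).
#' @param elevated_temp storage temperature, degC (default 85).
#' @param q10 reaction-rate coefficient per 10 degC (default 2).
#' @param duty fraction of time at the elevated temperature (default 162/168).
#' @return object of class `aging_protocol`.
#' @export
aging_protocol <- function(working_temp = 39, elevated_temp = 85, q10 = 2,
                           duty = 162 / 168) {
  if (!is.finite(q10) || q10 <= 1) stop("q10 must be > 1")
  if (!is.finite(duty) || duty <= 0 || duty > 1) stop("duty must be in (0, 1]")
  if (elevated_temp < working_temp)
    stop("elevated_temp must be >= working_temp")
  structure(list(working_temp = working_temp, elevated_temp = elevated_temp,
                 q10 = q10, duty = duty), class = "aging_protocol")
}

#' Arrhenius acceleration factor
#'
#' `AF = q10^((elevated - working)/10) * duty`. With the defaults this is
#' 2^4.6 x 162/168 = 23.386, reported to one decimal as 23.4 (truncating
#' instead of rounding would print 23.3).
#'
#' @param protocol an [aging_protocol()].
#' @return dimensionless acceleration factor (unrounded).
#' @export
acceleration_factor <- function(protocol = aging_protocol()) {
  stopifnot(inherits(protocol, "aging_protocol"))
  protocol$q10^((protocol$elevated_temp - protocol$working_temp) / 10) *
    protocol$duty
}

#' Real-time-equivalent duration of an accelerated test
#'
#' Maps elapsed rig time to equivalent working-temperature time:
#' `weeks * AF`, converted to years with a 365.25-day year. 22 weeks at the
#' default protocol represent about 10 years.
#'
#' @param real_duration_weeks elapsed accelerated-test duration in weeks.
#' @param protocol an [aging_protocol()].
#' @return equivalent duration in years.
#' @export
equivalent_duration <- function(real_duration_weeks,
                                protocol = aging_protocol()) {
  if (any(!is.finite(real_duration_weeks)) || any(real_duration_weeks <= 0))
    stop("real_duration_weeks must be > 0")
  real_duration_weeks * acceleration_factor(protocol) * 7 / 365.25
}

#' Inverse of [equivalent_duration()]
#' @param equivalent_years equivalent working-temperature duration, years.
#' @param protocol an [aging_protocol()].
#' @return required accelerated-test duration in weeks.
#' @export
required_test_weeks <- function(equivalent_years,
                                protocol = aging_protocol()) {
  equivalent_years * 365.25 / 7 / acceleration_factor(protocol)
}

#' Zero-point error of one drift-rig record
#'
#' Implant absolute pressure minus the reference (calibrated barometer plus
#' the fixed fluid-head column at 0.73559 mmHg/cm).
#'
#' @param implant_abs_pressure implant absolute reading, mmHg.
#' @param barometer barometer reading, mmHg (required; never assumed).
#' @param head_cm fluid column above the implant, cm.
#' @return zero-point error, mmHg.
#' @export
zero_point_error <- function(implant_abs_pressure, barometer, head_cm = 0) {
  if (missing(barometer) || any(is.na(barometer)))
    stop("barometer reading is required (never assumed)")
  implant_abs_pressure - (barometer + head_cm * CM_FLUID_TO_MMHG)
}

#' Zero-point drift series for one implant
#'
#' Per-reading zero-point error re-referenced to the first reading
#' (subtracting the t = 0 value), so the series starts at exactly 0 and
#' tracks sensor drift only.
#'
#' @param log drift-log data frame with columns `timestamp`, `implant_id`,
#'   `implant_abs_pressure`, `barometer`, `head_cm`.
#' @param implant_id which implant to extract.
#' @return data frame: `timestamp`, `t_days` (since first reading),
#'   `zero_point` (mmHg).
#' @export
zero_point_series <- function(log, implant_id) {
  rows <- log[log$implant_id == implant_id, , drop = FALSE]
  if (nrow(rows) == 0) stop("unknown implant_id: ", implant_id)
  rows <- rows[order(rows$timestamp), , drop = FALSE]
  err <- zero_point_error(rows$implant_abs_pressure, rows$barometer,
                          rows$head_cm)
  t0 <- rows$timestamp[1]
  data.frame(timestamp = rows$timestamp,
             t_days = as.numeric(difftime(rows$timestamp, t0, units = "days")),
             zero_point = err - err[1])
}

#' Qualify a zero-point drift series against a limit
#'
#' Pass means the maximum absolute zero-point excursion over the series stays
#' below the limit (per-implant maximum, the conservative reading of a
#' "drift < limit" claim).
#'
#' @param series data frame from [zero_point_series()] (needs `zero_point`
#'   and `timestamp`).
#' @param limit_mmhg drift limit, mmHg (default 2, the one-year claim).
#' @return list: `pass`, `max_excursion_mmhg`, `at` (timestamp of the
#'   excursion).
#' @export
drift_qualify <- function(series, limit_mmhg = 2) {
  if (nrow(series) == 0) stop("empty drift series")
  i <- which.max(abs(series$zero_point))
  exc <- abs(series$zero_point[i])
  list(pass = exc < limit_mmhg, max_excursion_mmhg = exc,
       at = series$timestamp[i])
}

#' Least-squares drift rate of a zero-point series
#'
#' Ordinary least squares of zero-point error on elapsed time, reported in
#' mmHg/year with its standard error.
#'
#' @param series data frame from [zero_point_series()].
#' @return list: `rate_mmhg_per_year`, `se`, `fit` (the `lm` object).
#' @export
drift_rate_fit <- function(series) {
  if (nrow(series) < 3) stop("need at least 3 readings to fit a drift rate")
  t_years <- series$t_days / 365.25
  fit <- stats::lm(series$zero_point ~ t_years)
  co <- summary(fit)$coefficients
  list(rate_mmhg_per_year = unname(co["t_years", "Estimate"]),
       se = unname(co["t_years", "Std. Error"]), fit = fit)
}

#' NS28-derived accuracy tolerances
#'
#' @param pressure_tol absolute pressure tolerance, mmHg (default 2).
#' @param temp_tol temperature tolerance, degC (default 2).
#' @param pressure_range required tested pressure span, mmHg
#'   (default 475-950 absolute).
#' @param temp_range required tested temperature span, degC (default 35-45).
#' @return object of class `tolerance_spec`.
#' @export
tolerance_spec <- function(pressure_tol = 2, temp_tol = 2,
                           pressure_range = c(475, 950),
                           temp_range = c(35, 45)) {
  if (pressure_tol <= 0 || temp_tol <= 0) stop("tolerances must be > 0")
  if (diff(pressure_range) <= 0 || diff(temp_range) <= 0)
    stop("ranges must be ordered (low, high)")
  structure(list(pressure_tol = pressure_tol, temp_tol = temp_tol,
                 pressure_range = pressure_range, temp_range = temp_range),
            class = "tolerance_spec")
}

#' Evaluate an accuracy grid against tolerances
#'
#' Per-cell error is reading minus set point, for the pressure and
#' temperature channels alike. The grid must span the required ranges
#' (a coverage failure is reported separately from a tolerance failure);
#' overall pass requires every cell within both tolerances.
#'
#' @param grid data frame with columns `set_pressure`, `set_temp`,
#'   `pressure_reading`, `temp_reading`.
#' @param tol a [tolerance_spec()].
#' @return list: `pass`, `coverage_ok`, `cells` (per-cell errors and flags),
#'   `summary` (n, mean and SD of each error channel), `failed_cells`.
#' @export
accuracy_evaluate <- function(grid, tol = tolerance_spec()) {
  required <- c("set_pressure", "set_temp", "pressure_reading", "temp_reading")
  missing_cols <- setdiff(required, names(grid))
  if (length(missing_cols))
    stop("accuracy grid is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  coverage_ok <-
    min(grid$set_pressure) <= tol$pressure_range[1] + 1e-9 &&
    max(grid$set_pressure) >= tol$pressure_range[2] - 1e-9 &&
    min(grid$set_temp) <= tol$temp_range[1] + 1e-9 &&
    max(grid$set_temp) >= tol$temp_range[2] - 1e-9
  cells <- data.frame(
    set_pressure = grid$set_pressure, set_temp = grid$set_temp,
    pressure_error = grid$pressure_reading - grid$set_pressure,
    temp_error = grid$temp_reading - grid$set_temp)
  cells$pressure_ok <- abs(cells$pressure_error) <= tol$pressure_tol
  cells$temp_ok <- abs(cells$temp_error) <= tol$temp_tol
  cells$ok <- cells$pressure_ok & cells$temp_ok
  summary <- data.frame(
    channel = c("pressure_mmhg", "temp_c"),
    n = nrow(cells),
    mean_error = c(mean(cells$pressure_error), mean(cells$temp_error)),
    sd_error = c(stats::sd(cells$pressure_error), stats::sd(cells$temp_error)))
  list(pass = coverage_ok && all(cells$ok),
       coverage_ok = coverage_ok,
       cells = cells,
       summary = summary,
       failed_cells = which(!cells$ok))
}
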