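#' SAR exposure scenario
#'
#' Holds the continuous (always-on) peak spatial-average SAR and total
#' absorbed power of a wand placement, the exposure duration, and the IEEE
#' C95.1 averaging windows and limits: peak spatial SAR is averaged over 6
#' minutes against a 2 W/kg limit (any 10 g of tissue); whole-body SAR is
#' total absorbed power per body mass averaged over 30 minutes against
#' 0.08 W/kg.
#'
#' @param psar_continuous continuous peak spatial-average SAR, W/kg.
#' @param absorbed_power total absorbed power, W.
#' @param measurement_s exposure (measurement) duration, seconds; the wand
#'   allows at most 120 s.
#' @param body_mass body mass in kg, optional (`NA` if unknown).
#' @param psar_window_s peak-SAR averaging window (default 360 s).
#' @param wb_window_s whole-body averaging window (default 1800 s).
#' @param psar_limit peak spatial SAR limit, W/kg (default 2).
#' @param wb_limit whole-body SAR limit, W/kg (default 0.08).
#' @return object of class `sar_exposure`.
#' @export
sar_exposure <- function(psar_continuous, absorbed_power,
                         measurement_s = 120, body_mass = NA_real_,
                         psar_window_s = 360, wb_window_s = 1800,
                         psar_limit = 2, wb_limit = 0.08) {
  if (!is.finite(psar_continuous) || psar_continuous < 0)
    stop("psar_continuous must be >= 0 W/kg")
  if (!is.finite(absorbed_power) || absorbed_power < 0)
    stop("absorbed_power must be >= 0 W")
  if (!is.finite(measurement_s) || measurement_s < 0)
    stop("measurement_s must be >= 0 s")
  if (psar_window_s <= 0 || wb_window_s <= 0) stop("windows must be > 0 s")
  structure(list(psar_continuous = psar_continuous,
                 absorbed_power = absorbed_power,
                 measurement_s = measurement_s,
                 body_mass = body_mass,
                 psar_window_s = psar_window_s, wb_window_s = wb_window_s,
                 psar_limit = psar_limit, wb_limit = wb_limit),
            class = "sar_exposure")
}

#' Time-averaged peak spatial SAR
#'
#' A single measurement of `measurement_s` seconds inside the 6-minute
#' averaging window scales the continuous SAR by the duty within the window:
#' `psar * min(measurement_s, window) / window`.
#'
#' @param exposure a [sar_exposure()].
#' @return averaged peak spatial SAR, W/kg (unrounded).
#' @export
psar_time_average <- function(exposure) {
  stopifnot(inherits(exposure, "sar_exposure"))
  exposure$psar_continuous *
    min(exposure$measurement_s, exposure$psar_window_s) / exposure$psar_window_s
}

#' Minimum body mass compliant with the whole-body SAR limit
#'
#' Whole-body SAR is absorbed power over mass, averaged over 30 minutes;
#' solving the limit for mass gives
#' `mass >= power * min(measurement_s, window) / window / limit`.
#'
#' @param exposure a [sar_exposure()].
#' @return minimum safe mass, kg (0 when no power is absorbed).
#' @export
min_safe_mass <- function(exposure) {
  stopifnot(inherits(exposure, "sar_exposure"))
  if (exposure$absorbed_power == 0) return(0)
  exposure$absorbed_power *
    min(exposure$measurement_s, exposure$wb_window_s) / exposure$wb_window_s /
    exposure$wb_limit
}

#' Maximum measurement duration under the whole-body limit
#'
#' Inverse of [min_safe_mass()]: `t <= limit * mass * window / power`. The
#' bound is capped at the averaging window (flagged unconstrained) and, for
#' reporting, at the device maximum of 120 s.
#'
#' @param exposure a [sar_exposure()] with `body_mass` set.
#' @param device_max_s hardware cap on a single measurement (default 120 s).
#' @return list: `t_max_s` (raw bound, capped at the window),
#'   `unconstrained` (TRUE when the window cap binds),
#'   `t_max_device_s` (additionally capped at `device_max_s`).
#' @export
max_measurement_time <- function(exposure, device_max_s = 120) {
  stopifnot(inherits(exposure, "sar_exposure"))
  if (!is.finite(exposure$body_mass) || exposure$body_mass <= 0)
    stop("body_mass must be > 0 kg")
  if (exposure$absorbed_power <= 0) stop("absorbed_power must be > 0 W")
  raw <- exposure$wb_limit * exposure$body_mass * exposure$wb_window_s /
    exposure$absorbed_power
  unconstrained <- raw >= exposure$wb_window_s
  t_max <- min(raw, exposure$wb_window_s)
  list(t_max_s = t_max, unconstrained = unconstrained,
       t_max_device_s = min(t_max, device_max_s))
}

#' Compliance report over an exposure table
#'
#' Applies the duty-cycle averaging to each row and checks the averaged peak
#' spatial SAR against its limit; when body mass is present the whole-body
#' limit is also checked. Values are exact internally; the report rounds
#' W/kg to 2 decimals and mass to the nearest 0.05 kg.
#'
#' @param exposures data frame with columns `model_name`,
#'   `psar_continuous_wkg`, `absorbed_power_w`, `measurement_s` and
#'   optionally `body_mass_kg`.
#' @param json_path,csv_path optional output files (JSON and CSV).
#' @return data frame: inputs plus `psar_avg_wkg`, `min_safe_mass_kg`,
#'   `wb_sar_avg_wkg` (NA without mass), `psar_pass`, `wb_pass`, `pass`.
#' @export
compliance_report <- function(exposures, json_path = NULL, csv_path = NULL) {
  required <- c("model_name", "psar_continuous_wkg", "absorbed_power_w",
                "measurement_s")
  if (!is.data.frame(exposures)) stop("exposures must be a data frame")
  missing_cols <- setdiff(required, names(exposures))
  if (length(missing_cols))
    stop("exposure table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(exposures)
  out <- exposures
  out$psar_avg_wkg <- rep(NA_real_, n)
  out$min_safe_mass_kg <- rep(NA_real_, n)
  out$wb_sar_avg_wkg <- rep(NA_real_, n)
  out$psar_pass <- rep(NA, n)
  out$wb_pass <- rep(NA, n)
  for (i in seq_len(n)) {
    row <- exposures[i, ]
    bad <- !is.finite(row$psar_continuous_wkg) ||
      !is.finite(row$absorbed_power_w) || !is.finite(row$measurement_s) ||
      row$psar_continuous_wkg < 0 || row$absorbed_power_w < 0 ||
      row$measurement_s < 0
    if (bad) stop("malformed exposure row at index ", i)
    mass <- if ("body_mass_kg" %in% names(exposures)) row$body_mass_kg else NA_real_
    ex <- sar_exposure(row$psar_continuous_wkg, row$absorbed_power_w,
                       measurement_s = row$measurement_s, body_mass = mass)
    out$psar_avg_wkg[i] <- psar_time_average(ex)
    out$min_safe_mass_kg[i] <- min_safe_mass(ex)
    out$psar_pass[i] <- out$psar_avg_wkg[i] < ex$psar_limit
    if (is.finite(mass) && mass > 0) {
      out$wb_sar_avg_wkg[i] <- ex$absorbed_power / mass *
        min(ex$measurement_s, ex$wb_window_s) / ex$wb_window_s
      out$wb_pass[i] <- out$wb_sar_avg_wkg[i] < ex$wb_limit
    }
  }
  out$pass <- out$psar_pass & (is.na(out$wb_pass) | out$wb_pass)
  report <- out
  report$psar_avg_wkg <- round(report$psar_avg_wkg, 2)
  report$wb_sar_avg_wkg <- round(report$wb_sar_avg_wkg, 4)
  report$min_safe_mass_kg <- round(report$min_safe_mass_kg / 0.05) * 0.05
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  if (!is.null(csv_path))
    utils::write.csv(report, csv_path, row.names = FALSE)
  out
}

#' Packaged worst-case SAR exposure table
#'
#' The three simulated worst-case wand placements (adult plus two paediatric
#' anatomical models) with their continuous peak spatial SAR and total
#' absorbed power, at the 120 s maximum measurement. Shipped as
#' `inst/extdata/sar_worst_case.csv`; columns are positional (model names as
#' printed in the source table headers are not authoritative).
#'
#' @return data frame ready for [compliance_report()].
#' @export
sar_worst_case_table <- function() {
  path <- system.file("extdata", "sar_worst_case.csv",
                      package = "icptelemetry", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
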