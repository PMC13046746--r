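#' Per-reading ICP pulse metrics
#'
#' Computes the clinical per-reading metrics from a 50 Hz pressure series:
#' mean ICP, the amplitude of the cardiac-related pulse wave, and a heart
#' rate estimate. The cardiac component is isolated with a zero-phase
#' (forward-backward) Butterworth band-pass (order 2, default 0.67-3.0 Hz,
#' i.e. 40-180 bpm); beats are segmented by peak detection on the filtered
#' signal and the amplitude is the median over beats of peak minus following
#' trough. Heart rate comes from the median inter-peak interval, computed in
#' Theil-Sen form over all peak pairs with sub-sample (parabolic) peak
#' timing. A spectral single-bin mode is available as a cross-check.
#'
#' @param rec an `icp_recording` (from [gen_icp()]) or a list with `samples`
#'   (mmHg) and `fs` (Hz).
#' @param band cardiac band in Hz, inside (0, fs/2).
#' @param mode `"beat"` (per-beat peak-to-trough median, canonical) or
#'   `"spectral"` (dominant-bin amplitude).
#' @return list of class `pulse_metrics`: `mean_icp`, `pulse_amplitude`
#'   (mmHg peak-to-trough), `heart_rate_est` (bpm), `n_beats`,
#'   `quality_flag` (`ok`, `low_beats` or `aliased`).
#' @export
pulse_metrics <- function(rec, band = c(0.67, 3.0),
                          mode = c("beat", "spectral")) {
  mode <- match.arg(mode)
  x <- rec$samples; fs <- rec$fs
  if (is.null(x) || is.null(fs)) stop("recording needs samples and fs")
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("band must lie within (0, fs/2) and be ordered")
  if (length(x) < 5 * fs)
    stop("recording shorter than 5 s; too short for amplitude estimation")
  mean_icp <- mean(x)

  if (stats::sd(x) == 0) {
    return(structure(list(mean_icp = mean_icp, pulse_amplitude = 0,
                          heart_rate_est = NA_real_, n_beats = 0L,
                          quality_flag = "low_beats"),
                     class = "pulse_metrics"))
  }

  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x - mean_icp)

  # beat segmentation regardless of mode (drives HR and quality)
  min_dist <- max(2L, floor(fs / band[2]))
  pk <- pracma::findpeaks(xf, minpeakdistance = min_dist,
                          minpeakheight = 0.1 * max(abs(xf)))
  peaks <- if (is.null(pk)) integer(0) else sort(pk[, 2])
  n_beats <- length(peaks)

  amps <- numeric(0)
  if (n_beats >= 2) {
    for (i in seq_len(n_beats - 1)) {
      seg <- xf[peaks[i]:peaks[i + 1]]
      amps <- c(amps, xf[peaks[i]] - min(seg))
    }
  }
  # sub-sample peak locations by parabolic interpolation: quantizing peaks
  # to whole samples biases the median interval by up to half a sample,
  # i.e. ~1.4 bpm at 50 Hz / 70 bpm
  pk_t <- as.numeric(peaks)
  for (j in seq_along(peaks)) {
    p <- peaks[j]
    if (p > 1L && p < length(xf)) {
      denom <- xf[p - 1] - 2 * xf[p] + xf[p + 1]
      if (denom < 0) pk_t[j] <- p + 0.5 * (xf[p - 1] - xf[p + 1]) / denom
    }
  }
  hr <- NA_real_
  if (n_beats >= 2) {
    # median inter-peak interval, Theil-Sen form: the median over all peak
    # pairs of (gap / beats spanned). Adjacent-interval medians inherit the
    # full peak-timing jitter (~1 bpm at this noise level); pairwise gaps
    # divide it by the span. Beat counts per gap come from the provisional
    # adjacent-interval median so that a missed beat cannot bias the lag.
    t0 <- stats::median(diff(pk_t))
    gaps <- outer(pk_t, pk_t, "-")
    gaps <- gaps[lower.tri(gaps)]
    k <- round(gaps / t0)
    ok <- k >= 1
    hr <- 60 * fs / stats::median(gaps[ok] / k[ok])
  }

  amplitude <- if (mode == "spectral") {
    n <- length(xf)
    sp <- Mod(stats::fft(x - mean_icp))[seq_len(floor(n / 2))]
    freqs <- (seq_len(floor(n / 2)) - 1) * fs / n
    in_band <- freqs >= band[1] & freqs <= band[2]
    if (!any(in_band)) 0 else 4 * max(sp[in_band]) / n
  } else if (length(amps)) stats::median(amps) else 0

  flag <- "ok"
  if (n_beats < 5) flag <- "low_beats"
  else if (is.finite(hr) &&
           (hr / 60 <= band[1] * 1.02 || hr / 60 >= band[2] * 0.98))
    flag <- "aliased"

  structure(list(mean_icp = mean_icp, pulse_amplitude = amplitude,
                 heart_rate_est = hr, n_beats = as.integer(n_beats),
                 quality_flag = flag),
            class = "pulse_metrics")
}

#' @export
print.pulse_metrics <- function(x, ...) {
  cat(sprintf("pulse_metrics: mean ICP %.2f mmHg, pulse amplitude %.2f mmHg, HR %.1f bpm (%d beats, %s)\n",
              x$mean_icp, x$pulse_amplitude, x$heart_rate_est, x$n_beats,
              x$quality_flag))
  invisible(x)
}

#' One diary row per recording
#'
#' Collapses a recording to the longitudinal-table row: timestamp, posture,
#' mean ICP and pulse amplitude. Negative mean ICP is legitimate (upright
#' postures).
#'
#' @param rec an `icp_recording`.
#' @param band,mode passed to [pulse_metrics()].
#' @return one-row data frame: `timestamp`, `patient_id`, `posture`,
#'   `mean_icp`, `pulse_amplitude`, `heart_rate_est`, `quality_flag`.
#' @export
reading_summary <- function(rec, band = c(0.67, 3.0), mode = "beat") {
  pm <- pulse_metrics(rec, band = band, mode = mode)
  posture <- rec$posture
  posture <- if (is.null(posture) || !length(posture)) "unspecified" else {
    tab <- table(posture)
    names(tab)[which.max(tab)]
  }
  if (!nzchar(posture) || is.na(posture)) posture <- "unspecified"
  data.frame(timestamp = rec$start_time,
             patient_id = if (is.null(rec$patient_id)) "unspecified" else rec$patient_id,
             posture = posture,
             mean_icp = pm$mean_icp,
             pulse_amplitude = pm$pulse_amplitude,
             heart_rate_est = pm$heart_rate_est,
             quality_flag = pm$quality_flag,
             stringsAsFactors = FALSE)
}

#' Posture-stratified longitudinal summary
#'
#' Bins diary rows into consecutive windows per posture and reports the
#' median and interquartile range of mean ICP and pulse amplitude per
#' window, plus a stability statistic: the largest deviation of any window
#' median from the posture's global median.
#'
#' @param rows data frame of [reading_summary()] rows.
#' @param window_days window length in days (default 30).
#' @return list: `windows` (per posture x window medians and IQRs),
#'   `stability` (per posture, mmHg).
#' @export
longitudinal_summary <- function(rows, window_days = 30) {
  if (nrow(rows) == 0) stop("no diary rows")
  t0 <- min(rows$timestamp)
  rows$window <- floor(as.numeric(difftime(rows$timestamp, t0,
                                           units = "days")) / window_days)
  sp <- split(rows, list(rows$posture, rows$window), drop = TRUE)
  windows <- do.call(rbind, lapply(sp, function(g) data.frame(
    posture = g$posture[1], window = g$window[1], n = nrow(g),
    median_icp = stats::median(g$mean_icp),
    iqr_icp = stats::IQR(g$mean_icp),
    median_amplitude = stats::median(g$pulse_amplitude),
    iqr_amplitude = stats::IQR(g$pulse_amplitude))))
  windows <- windows[order(windows$posture, windows$window), ]
  rownames(windows) <- NULL
  stability <- vapply(split(rows, rows$posture), function(g) {
    gm <- stats::median(g$mean_icp)
    wm <- tapply(g$mean_icp, floor(as.numeric(
      difftime(g$timestamp, t0, units = "days")) / window_days),
      stats::median)
    max(abs(wm - gm))
  }, numeric(1))
  list(windows = windows, stability = stability)
}

#' Flag mean-ICP excursions against a per-posture rolling baseline
#'
#' Purely descriptive (not a diagnostic claim): a reading is flagged when its
#' mean ICP deviates from the median of same-posture readings in the trailing
#' baseline window by more than `k` times that baseline's IQR. Readings with
#' fewer than `min_baseline` baseline points are reported as not evaluable.
#'
#' @param rows diary rows ([reading_summary()] schema).
#' @param baseline_window_days trailing window length, days; must be shorter
#'   than the diary span.
#' @param k IQR multiplier (default 3).
#' @param min_baseline minimum baseline readings (default 3).
#' @return `rows` plus `baseline_median`, `baseline_iqr`, `status`
#'   (`ok`/`flagged`/`not_evaluable`).
#' @export
excursion_flags <- function(rows, baseline_window_days = 30, k = 3,
                            min_baseline = 3) {
  if (nrow(rows) == 0) stop("no diary rows")
  span <- as.numeric(difftime(max(rows$timestamp), min(rows$timestamp),
                              units = "days"))
  if (baseline_window_days >= span)
    stop("baseline_window_days (", baseline_window_days,
         ") must be shorter than the diary span (", round(span, 1), " days)")
  rows <- rows[order(rows$timestamp), ]
  out <- rows
  out$baseline_median <- NA_real_
  out$baseline_iqr <- NA_real_
  out$status <- "not_evaluable"
  for (i in seq_len(nrow(rows))) {
    t_i <- rows$timestamp[i]
    sel <- rows$posture == rows$posture[i] &
      rows$timestamp < t_i &
      rows$timestamp >= t_i - baseline_window_days * 86400
    if (sum(sel) < min_baseline) next
    bm <- stats::median(rows$mean_icp[sel])
    biqr <- stats::IQR(rows$mean_icp[sel])
    out$baseline_median[i] <- bm
    out$baseline_iqr[i] <- biqr
    out$status[i] <- if (abs(rows$mean_icp[i] - bm) > k * biqr)
      "flagged" else "ok"
  }
  out
}
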