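#!/usr/bin/env Rscript
# Stage 5: ICP waveform analytics over the simulated home-monitoring diary:
# per-reading pulse metrics, posture-stratified longitudinal windows, and
# excursion flags against a trailing same-posture baseline.

library(icptelemetry)

out <- file.path("results", "icp")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
sim <- file.path("results", "simulate")

samples <- read_table_csv(file.path(sim, "icp_samples.csv"),
                          required = c("reading_id", "t_s", "pressure_mmhg"))
readings <- read_table_csv(file.path(sim, "icp_readings.csv"),
                           required = c("reading_id", "timestamp",
                                        "patient_id", "fs_hz", "posture"))

rows <- do.call(rbind, lapply(seq_len(nrow(readings)), function(i) {
  meta <- readings[i, ]
  x <- samples$pressure_mmhg[samples$reading_id == meta$reading_id]
  rec <- structure(list(samples = x, fs = meta$fs_hz,
                        t_s = (seq_along(x) - 1) / meta$fs_hz,
                        posture = rep(meta$posture, length(x)),
                        start_time = meta$timestamp,
                        patient_id = meta$patient_id),
                   class = "icp_recording")
  reading_summary(rec, band = c(0.67, 3.0))
}))
write_table_csv(rows, file.path(out, "diary.csv"))
cat(sprintf("diary: %d readings, %d below quality\n",
            nrow(rows), sum(rows$quality_flag != "ok")))

ls <- longitudinal_summary(rows, window_days = 30)
write.csv(ls$windows, file.path(out, "longitudinal_windows.csv"),
          row.names = FALSE)
print(ls$windows)

fl <- excursion_flags(rows, baseline_window_days = 45, k = 3)
write_table_csv(fl, file.path(out, "excursion_flags.csv"))

jsonlite::write_json(
  list(stability_mmhg = as.list(ls$stability),
       n_flagged = sum(fl$status == "flagged"),
       median_amplitude_mmhg = median(rows$pulse_amplitude),
       median_hr_bpm = median(rows$heart_rate_est, na.rm = TRUE)),
  file.path(out, "icp_summary.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat(sprintf("median pulse amplitude %.2f mmHg, %d excursions flagged\n",
            median(rows$pulse_amplitude), sum(fl$status == "flagged")))
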