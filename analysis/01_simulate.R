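#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input of the study and persist it under
# results/simulate/. All downstream scripts read only these files.

library(icptelemetry)

seed <- 1
out <- file.path("results", "simulate")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## head surface: adult-sized ellipsoid, 5 mm mesh resolution
mesh <- gen_head_mesh(head_mesh_spec("ellipsoid", semi_axes = c(70, 90, 80),
                                     mesh_resolution = 5))
print(mesh)
write_mesh(mesh, file.path(out, "head.ply"))
write_mesh(mesh, file.path(out, "head.stl"))

## drift rig: 16 implants, one year, 0.5 mmHg/yr injected drift
drift <- gen_drift_log(drift_sim_spec(
  n_implants = 16, duration_weeks = 52, read_interval = 1,
  true_drift_rate = 0.5, noise_sd = 0.2, seed = seed))
write_table_csv(drift, file.path(out, "drift_log.csv"))
cat(sprintf("drift log: %d records, %d implants\n",
            nrow(drift), length(unique(drift$implant_id))))

## accuracy rig: full factorial 42 x 11 grid, uniform(-1, 1) errors
grid <- gen_accuracy_grid(error_model = uniform_error_model(1, 1),
                          seed = seed + 1)
write_table_csv(grid, file.path(out, "accuracy_grid.csv"))
cat(sprintf("accuracy grid: %d cells\n", nrow(grid)))

## home-monitoring diary: 60 standard reads over 180 days, three postures
postures <- data.frame(posture = c("lying", "sitting", "standing"),
                       mean_icp = c(12, 2, -8))
t0 <- as.POSIXct("2024-01-01 08:00:00", tz = "UTC")
n_readings <- 60
samples <- vector("list", n_readings)
readings <- vector("list", n_readings)
for (i in seq_len(n_readings)) {
  po <- postures[((i - 1) %% nrow(postures)) + 1, ]
  rec <- gen_icp(icp_sim_spec(mean_icp = po$mean_icp, pulse_amp = 2,
                              heart_rate = 70, noise_sd = 0.2,
                              seed = seed + 100 + i),
                 start_time = t0 + (i - 1) / n_readings * 180 * 86400,
                 patient_id = "synthetic_01")
  samples[[i]] <- data.frame(reading_id = i, t_s = rec$t_s,
                             pressure_mmhg = rec$samples)
  readings[[i]] <- data.frame(reading_id = i, timestamp = rec$start_time,
                              patient_id = rec$patient_id, fs_hz = rec$fs,
                              posture = po$posture)
}
write_table_csv(do.call(rbind, samples), file.path(out, "icp_samples.csv"))
write_table_csv(do.call(rbind, readings), file.path(out, "icp_readings.csv"))
cat(sprintf("icp diary: %d readings of %d samples\n",
            n_readings, length(samples[[1]]$t_s)))
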