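#!/usr/bin/env Rscript
# Stage 3: SAR compliance of the packaged worst-case exposure table
# (adult and two paediatric models) at the 120 s maximum measurement,
# under IEEE C95.1 time averaging.

library(icptelemetry)

out <- file.path("results", "sar")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- sar_worst_case_table()
rep <- compliance_report(tab,
                         json_path = file.path(out, "report.json"),
                         csv_path = file.path(out, "report.csv"))
print(rep[, c("model_name", "psar_continuous_wkg", "psar_avg_wkg",
              "min_safe_mass_kg", "pass")])

# measurement-time bounds for representative body masses
masses <- data.frame(subject = c("neonate_3kg", "infant_6kg", "adult_70kg"),
                     body_mass_kg = c(3, 6, 70))
worst <- tab[which.max(tab$absorbed_power_w), ]
masses$t_max_s <- vapply(masses$body_mass_kg, function(m) {
  max_measurement_time(sar_exposure(worst$psar_continuous_wkg,
                                    worst$absorbed_power_w,
                                    body_mass = m))$t_max_device_s
}, numeric(1))
write.csv(masses, file.path(out, "measurement_time_bounds.csv"),
          row.names = FALSE)
print(masses)
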