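#!/usr/bin/env Rscript
# Stage 4: sensor qualification. Zero-point drift of the simulated rig
# cohort against the 2 mmHg one-year limit, accuracy-grid evaluation against
# the +-2 mmHg / +-2 degC tolerances, and the Q10 accelerated-aging mapping.

library(icptelemetry)

out <- file.path("results", "qualification")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
sim <- file.path("results", "simulate")

## zero-point drift per implant
log <- read_table_csv(file.path(sim, "drift_log.csv"),
                      required = c("timestamp", "implant_id",
                                   "implant_abs_pressure", "barometer",
                                   "head_cm"))
drift <- do.call(rbind, lapply(unique(log$implant_id), function(id) {
  s <- zero_point_series(log, id)
  q <- drift_qualify(s, limit_mmhg = 2)
  f <- drift_rate_fit(s)
  data.frame(implant_id = id, pass = q$pass,
             max_excursion_mmhg = q$max_excursion_mmhg,
             rate_mmhg_per_year = f$rate_mmhg_per_year, rate_se = f$se)
}))
write.csv(drift, file.path(out, "drift_qualification.csv"), row.names = FALSE)
cat(sprintf("drift: %d/%d implants pass; median fitted rate %.2f mmHg/yr\n",
            sum(drift$pass), nrow(drift), median(drift$rate_mmhg_per_year)))

## accuracy grid
grid <- read_table_csv(file.path(sim, "accuracy_grid.csv"),
                       required = c("set_pressure", "set_temp",
                                    "pressure_reading", "temp_reading"))
acc <- accuracy_evaluate(grid, tolerance_spec())
write.csv(acc$cells, file.path(out, "accuracy_cells.csv"), row.names = FALSE)
cat(sprintf("accuracy: %s (%d cells, coverage %s)\n",
            if (acc$pass) "pass" else "FAIL", nrow(acc$cells),
            if (acc$coverage_ok) "ok" else "insufficient"))

## accelerated aging
protocol <- aging_protocol(working_temp = 39, elevated_temp = 85, q10 = 2,
                           duty = 162 / 168)
report <- list(
  drift = list(limit_mmhg = 2, n_implants = nrow(drift),
               n_pass = sum(drift$pass)),
  aging = list(acceleration_factor = acceleration_factor(protocol),
               acceleration_factor_1dp = round(acceleration_factor(protocol), 1),
               accelerated_weeks = 22,
               equivalent_years = equivalent_duration(22, protocol)),
  accuracy = list(pass = acc$pass, coverage_ok = acc$coverage_ok,
                  summary = acc$summary))
jsonlite::write_json(report, file.path(out, "qualification.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat(sprintf("aging: AF = %.1f; 22 accelerated weeks = %.2f equivalent years\n",
            report$aging$acceleration_factor_1dp,
            report$aging$equivalent_years))
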