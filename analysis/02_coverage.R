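#!/usr/bin/env Rscript
# Stage 2: wireless-power coverage map. Voxelizes the head from stage 1,
# places wand poses on the scalp and classifies every interior voxel against
# the 28 uT_RMS powering threshold under worst-case implant orientation.
# Reduced demonstration resolution (4 mm, 120 poses); the acceptance suite
# runs the 2 mm variant.

library(icptelemetry)

out <- file.path("results", "coverage")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mesh <- read_mesh(file.path("results", "simulate", "head.ply"))
map <- coverage_map(
  mesh,
  coil_template = coil_spec(radius = 0.075, amp_turns = 11),
  n_poses = 120, spacing_mm = 4, threshold_t = 28e-6,
  standoff_mm = 5, seed = 1)
print(map)

write_coverage_volume(map, out)
export_slice(map, "sagittal", path_prefix = file.path(out, "sagittal_mid"), png = FALSE)
export_slice(map, "axial", path_prefix = file.path(out, "axial_mid"), png = FALSE)

tab <- tabulate(map$class[!is.na(map$class)] + 1L, 3)
n_in <- sum(map$grid$inside_mask)
summary <- data.frame(
  class = c("always_powered", "orientation_dependent", "unreachable"),
  voxels = tab, fraction = tab / n_in)
write.csv(summary, file.path(out, "coverage_summary.csv"), row.names = FALSE)
print(summary)
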