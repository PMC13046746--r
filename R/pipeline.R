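# End-to-end reproducible pipeline: simulate -> coverage -> sar ->
# qualification -> icp, with a resolved-config snapshot, a provenance
# manifest and a run log in every output directory.

#' Default run configuration
#'
#' A complete, reduced-size demonstration configuration: every stage on
#' synthetic inputs, coverage at coarse resolution so a full run stays in the
#' minutes range on one CPU. Units are encoded in key names (`spacing_mm`,
#' `threshold_ut`, ...) to prevent unit bugs.
#'
#' @return nested named list (the `RunConfig`).
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    out_dir = "icptelemetry_run",
    log_level = "info",
    stages = c("simulate", "coverage", "sar", "qualification", "icp"),
    simulate = list(
      head = list(shape = "ellipsoid", semi_axes_mm = c(70, 90, 80),
                  mesh_resolution_mm = 8),
      drift = list(n_implants = 16, duration_weeks = 52, read_interval_days = 1,
                   true_drift_rate_mmhg_yr = 0.5, noise_sd_mmhg = 0.2,
                   head_height_cm = 1),
      accuracy = list(n_pressure = 42, n_temp = 11, error_max_mmhg = 1,
                      error_max_c = 1),
      icp = list(n_readings = 60, span_days = 180, pulse_amp_mmhg = 2,
                 heart_rate_bpm = 70, noise_sd_mmhg = 0.2,
                 postures = list(
                   list(posture = "lying", mean_icp_mmhg = 12),
                   list(posture = "sitting", mean_icp_mmhg = 2),
                   list(posture = "standing", mean_icp_mmhg = -8)))),
    coverage = list(n_poses = 120, spacing_mm = 4, threshold_ut = 28,
                    standoff_mm = 5, coil_radius_m = 0.075, amp_turns = 11,
                    direction_level = 4),
    sar = list(measurement_s = 120),
    qualification = list(drift_limit_mmhg = 2, accelerated_weeks = 22,
                         q10 = 2, working_c = 39, elevated_c = 85,
                         duty = 162 / 168),
    icp = list(band_hz = c(0.67, 3.0), window_days = 30,
               baseline_window_days = 45, k_iqr = 3))
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order on a fresh output directory,
#' logging to console and `run.log`, and writing `resolved_config.yaml`
#' before any computation and `manifest.json` (parameters, seed, package
#' version, output checksums) at the end. Any stage failure aborts with the
#' stage name; outputs of completed stages are preserved.
#'
#' @param config nested list as from [default_run_config()], or a path to a
#'   YAML file with the same structure. Unknown keys are rejected before any
#'   computation. Partial configs are merged over the defaults.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  config <- merge_config(default_run_config(), config, path = "config")
  bad <- setdiff(config$stages,
                 c("simulate", "coverage", "sar", "qualification", "icp"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))

  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "run.log")
  logger <- make_logger(logfile, config$log_level)
  yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))
  logger("info", "resolved config written; seed = ", config$seed)

  state <- list(config = config, out = out_dir, log = logger)
  for (stage in config$stages) {
    logger("info", "stage ", stage, " starting")
    state <- tryCatch(
      switch(stage,
             simulate = stage_simulate(state),
             coverage = stage_coverage(state),
             sar = stage_sar(state),
             qualification = stage_qualification(state),
             icp = stage_icp(state)),
      error = function(e) stop("stage '", stage, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    logger("info", "stage ", stage, " done")
  }

  # run.log is excluded: it receives lines after the checksums are taken
  files <- setdiff(list.files(out_dir, recursive = TRUE, full.names = TRUE),
                   file.path(out_dir, c("manifest.json", "run.log")))
  manifest <- list(
    package = "icptelemetry",
    version = as.character(utils::packageVersion("icptelemetry")),
    r_version = R.version.string,
    seed = config$seed,
    stages = config$stages,
    config_file = "resolved_config.yaml",
    outputs = data.frame(
      file = sub(paste0("^", out_dir, "/"), "", files),
      md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logger("info", "manifest written (", length(files), " outputs)")
  invisible(out_dir)
}

# strict recursive merge: keys absent from the defaults are rejected
merge_config <- function(defaults, user, path = "config") {
  if (is.null(user)) return(defaults)
  if (!is.list(user) || is.null(names(defaults))) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s) under ", path, ": ",
         paste(unknown, collapse = ", "))
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])))
      merge_config(defaults[[nm]], user[[nm]], paste(path, nm, sep = "$"))
    else user[[nm]]
  }
  defaults
}

make_logger <- function(logfile, level = "info") {
  ranks <- c(debug = 1, info = 2, warning = 3)
  min_rank <- ranks[[match.arg(level, names(ranks))]]
  function(lvl, ...) {
    if (ranks[[lvl]] < min_rank) return(invisible())
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " [", lvl, "] ",
                   paste0(..., collapse = ""))
    message(line)
    cat(line, "\n", file = logfile, append = TRUE)
  }
}

stage_simulate <- function(state) {
  cfg <- state$config
  sim <- cfg$simulate
  dir <- file.path(state$out, "simulate")
  dir.create(dir, showWarnings = FALSE)

  mesh <- gen_head_mesh(head_mesh_spec(
    shape = sim$head$shape, semi_axes = unlist(sim$head$semi_axes_mm),
    mesh_resolution = sim$head$mesh_resolution_mm))
  write_mesh(mesh, file.path(dir, "head.ply"))
  write_mesh(mesh, file.path(dir, "head.stl"))
  state$mesh <- mesh

  dl <- gen_drift_log(drift_sim_spec(
    n_implants = sim$drift$n_implants,
    duration_weeks = sim$drift$duration_weeks,
    read_interval = sim$drift$read_interval_days,
    true_drift_rate = sim$drift$true_drift_rate_mmhg_yr,
    noise_sd = sim$drift$noise_sd_mmhg,
    head_height_cm = sim$drift$head_height_cm,
    seed = cfg$seed))
  write_table_csv(dl, file.path(dir, "drift_log.csv"))
  state$drift_log <- dl

  grid <- gen_accuracy_grid(
    n_pressure = sim$accuracy$n_pressure, n_temp = sim$accuracy$n_temp,
    error_model = uniform_error_model(sim$accuracy$error_max_mmhg,
                                      sim$accuracy$error_max_c),
    seed = cfg$seed + 1)
  write_table_csv(grid, file.path(dir, "accuracy_grid.csv"))
  state$accuracy_grid <- grid

  icp_cfg <- sim$icp
  postures <- icp_cfg$postures
  rows <- list()
  t0 <- as.POSIXct("2024-01-01 08:00:00", tz = "UTC")
  for (i in seq_len(icp_cfg$n_readings)) {
    po <- postures[[((i - 1) %% length(postures)) + 1]]
    spec <- icp_sim_spec(duration_s = 10.08, mean_icp = po$mean_icp_mmhg,
                         pulse_amp = icp_cfg$pulse_amp_mmhg,
                         heart_rate = icp_cfg$heart_rate_bpm,
                         noise_sd = icp_cfg$noise_sd_mmhg,
                         seed = cfg$seed + 100 + i)
    rec <- gen_icp(spec, start_time = t0 +
                     (i - 1) / icp_cfg$n_readings * icp_cfg$span_days * 86400)
    rec$posture <- rep(po$posture, length(rec$samples))
    rows[[i]] <- rec
  }
  state$icp_recordings <- rows
  state$log("info", "simulated: mesh (", nrow(mesh$faces), " faces), ",
            nrow(dl), " drift records, ", nrow(grid), " accuracy cells, ",
            length(rows), " ICP readings")
  state
}

stage_coverage <- function(state) {
  cfg <- state$config$coverage
  dir <- file.path(state$out, "coverage")
  dir.create(dir, showWarnings = FALSE)
  mesh <- state$mesh
  if (is.null(mesh)) stop("coverage stage needs the simulate stage's mesh")
  map <- coverage_map(
    mesh,
    coil_template = coil_spec(radius = cfg$coil_radius_m,
                              amp_turns = cfg$amp_turns),
    n_poses = cfg$n_poses, spacing_mm = cfg$spacing_mm,
    threshold_t = cfg$threshold_ut * 1e-6,
    standoff_mm = cfg$standoff_mm, seed = state$config$seed,
    level = cfg$direction_level)
  write_coverage_volume(map, dir)
  export_slice(map, "sagittal", path_prefix = file.path(dir, "sagittal_mid"))
  n_in <- sum(map$grid$inside_mask)
  tab <- tabulate(map$class[!is.na(map$class)] + 1L, 3)
  state$log("info", sprintf(
    "coverage: %d voxels, %.1f%% always powered, %.1f%% orientation dependent, %.1f%% unreachable",
    n_in, 100 * tab[1] / n_in, 100 * tab[2] / n_in, 100 * tab[3] / n_in))
  state$coverage <- map
  state
}

stage_sar <- function(state) {
  dir <- file.path(state$out, "sar")
  dir.create(dir, showWarnings = FALSE)
  tab <- sar_worst_case_table()
  tab$measurement_s <- state$config$sar$measurement_s
  rep <- compliance_report(tab, json_path = file.path(dir, "report.json"),
                           csv_path = file.path(dir, "report.csv"))
  state$log("info", "sar: ", sum(rep$pass), "/", nrow(rep),
            " exposures compliant")
  state$sar_report <- rep
  state
}

stage_qualification <- function(state) {
  cfg <- state$config$qualification
  dir <- file.path(state$out, "qualification")
  dir.create(dir, showWarnings = FALSE)
  log <- state$drift_log
  if (is.null(log)) stop("qualification stage needs the simulate stage's drift log")

  ids <- unique(log$implant_id)
  drift <- do.call(rbind, lapply(ids, function(id) {
    s <- zero_point_series(log, id)
    q <- drift_qualify(s, cfg$drift_limit_mmhg)
    f <- drift_rate_fit(s)
    data.frame(implant_id = id, pass = q$pass,
               max_excursion_mmhg = q$max_excursion_mmhg,
               rate_mmhg_per_year = f$rate_mmhg_per_year, rate_se = f$se)
  }))
  utils::write.csv(drift, file.path(dir, "drift_qualification.csv"),
                   row.names = FALSE)

  protocol <- aging_protocol(cfg$working_c, cfg$elevated_c, cfg$q10, cfg$duty)
  acc <- accuracy_evaluate(state$accuracy_grid)
  utils::write.csv(acc$cells, file.path(dir, "accuracy_cells.csv"),
                   row.names = FALSE)
  report <- list(
    drift = list(limit_mmhg = cfg$drift_limit_mmhg,
                 n_implants = length(ids), n_pass = sum(drift$pass)),
    aging = list(acceleration_factor = acceleration_factor(protocol),
                 acceleration_factor_1dp = round(acceleration_factor(protocol), 1),
                 accelerated_weeks = cfg$accelerated_weeks,
                 equivalent_years = equivalent_duration(cfg$accelerated_weeks,
                                                        protocol)),
    accuracy = list(pass = acc$pass, coverage_ok = acc$coverage_ok,
                    summary = acc$summary))
  jsonlite::write_json(report, file.path(dir, "qualification.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  state$log("info", sprintf(
    "qualification: drift %d/%d pass, AF = %.1f, 22 wk = %.2f yr, accuracy %s",
    sum(drift$pass), length(ids), acceleration_factor(protocol),
    report$aging$equivalent_years, if (acc$pass) "pass" else "FAIL"))
  state$qualification <- report
  state
}

stage_icp <- function(state) {
  cfg <- state$config$icp
  dir <- file.path(state$out, "icp")
  dir.create(dir, showWarnings = FALSE)
  recs <- state$icp_recordings
  if (is.null(recs)) stop("icp stage needs the simulate stage's recordings")
  rows <- do.call(rbind, lapply(recs, reading_summary,
                                band = unlist(cfg$band_hz)))
  n_low <- sum(rows$quality_flag != "ok")
  if (n_low) state$log("warning", n_low, " low-quality recordings")
  write_table_csv(rows, file.path(dir, "diary.csv"))
  ls <- longitudinal_summary(rows, window_days = cfg$window_days)
  utils::write.csv(ls$windows, file.path(dir, "longitudinal_windows.csv"),
                   row.names = FALSE)
  fl <- excursion_flags(rows, baseline_window_days = cfg$baseline_window_days,
                        k = cfg$k_iqr)
  write_table_csv(fl, file.path(dir, "excursion_flags.csv"))
  jsonlite::write_json(
    list(stability_mmhg = as.list(ls$stability),
         n_flagged = sum(fl$status == "flagged"),
         median_amplitude_mmhg = stats::median(rows$pulse_amplitude)),
    file.path(dir, "icp_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  state$log("info", sprintf(
    "icp: %d readings, median pulse amplitude %.2f mmHg, %d flagged",
    nrow(rows), stats::median(rows$pulse_amplitude),
    sum(fl$status == "flagged")))
  state$icp_rows <- rows
  state
}
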