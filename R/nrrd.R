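# Minimal NRRD volume writer/reader (ASCII encoding), used to persist the
# coverage volumes with their grid metadata. The ASCII encoding keeps
# artifacts text-only and diff-able; readers elsewhere (pynrrd, ITK) accept
# it directly.

#' Write a 3-D array as an ASCII-encoded NRRD volume
#'
#' @param arr numeric or integer 3-D array (x fastest, R layout).
#' @param path output `.nrrd` file.
#' @param spacing scalar voxel spacing (mm).
#' @param origin length-3 grid origin (mm, corner convention as in
#'   [voxelize()]).
#' @param type `"double"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(arr, path, spacing = 1, origin = c(0, 0, 0),
                       type = c("double", "uint8")) {
  type <- match.arg(type)
  stopifnot(length(dim(arr)) == 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dim(arr), collapse = " ")),
    paste0("spacings: ", paste(rep(spacing, 3), collapse = " ")),
    paste0("axis mins: ", paste(origin, collapse = " ")),
    "encoding: ascii",
    ""), con)
  vals <- as.vector(arr)
  if (type == "uint8") {
    vals[is.na(vals)] <- 255
    writeLines(paste(as.integer(vals), collapse = " "), con)
  } else {
    writeLines(paste(sprintf("%.17g", vals), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ASCII-encoded NRRD volume written by [write_nrrd()]
#'
#' @param path `.nrrd` file.
#' @return 3-D array with attributes `spacing` and `origin`; uint8 value 255
#'   is mapped back to NA.
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1], "NRRD")) stop("not a NRRD file: ", path)
  blank <- which(lines == "")[1]
  hdr <- lines[2:(blank - 1)]
  field <- function(name) {
    ln <- hdr[startsWith(hdr, paste0(name, ":"))]
    if (!length(ln)) return(NULL)
    trimws(sub(paste0(name, ":"), "", ln[1], fixed = TRUE))
  }
  if (field("encoding") != "ascii") stop("only ascii-encoded NRRD is supported")
  sizes <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  type <- field("type")
  vals <- scan(text = paste(lines[(blank + 1):length(lines)], collapse = " "),
               quiet = TRUE)
  if (type == "uint8") vals[vals == 255] <- NA
  arr <- array(vals, dim = sizes)
  attr(arr, "spacing") <- as.numeric(strsplit(field("spacings"), "\\s+")[[1]])[1]
  org <- field("axis mins")
  attr(arr, "origin") <- if (is.null(org)) c(0, 0, 0) else
    as.numeric(strsplit(org, "\\s+")[[1]])
  arr
}

#' Persist a coverage map as NRRD volumes plus a JSON sidecar
#'
#' Writes `W.nrrd` and `M.nrrd` (tesla, double), `class.nrrd` (uint8:
#' 0 always_powered, 1 orientation_dependent, 2 unreachable, 255 outside)
#' and `grid.json` with grid, pose and threshold metadata.
#'
#' @param map a `coverage_map`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_coverage_volume <- function(map, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- map$grid
  write_nrrd(map$W, file.path(dir, "W.nrrd"), g$spacing, g$origin, "double")
  write_nrrd(map$M, file.path(dir, "M.nrrd"), g$spacing, g$origin, "double")
  cls <- map$class
  write_nrrd(cls, file.path(dir, "class.nrrd"), g$spacing, g$origin, "uint8")
  meta <- list(
    origin_mm = g$origin, spacing_mm = g$spacing, dims = g$dims,
    n_inside = sum(g$inside_mask),
    threshold_t = map$threshold,
    n_poses = length(map$pose_set$poses),
    n_poses_requested = map$pose_set$n_requested,
    standoff_mm = map$pose_set$standoff_mm,
    coil_radius_m = map$coil_template$radius,
    amp_turns = map$coil_template$amp_turns,
    direction_level = map$level, seed = map$seed,
    class_levels = c("always_powered", "orientation_dependent", "unreachable"))
  jsonlite::write_json(meta, file.path(dir, "grid.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
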