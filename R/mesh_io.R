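# Minimal STL / PLY readers and writers for triangle surface meshes.
# ASCII is the canonical fixture dialect; the binary dialects are also
# supported for interoperability. Units are whatever the mesh carries (mm
# throughout this package).

#' Write a surface mesh to STL or PLY
#'
#' @param mesh a `surface_mesh` (list with `vertices`, `faces`).
#' @param path output file; format inferred from the `.stl`/`.ply` extension
#'   unless `format` is given.
#' @param format `"stl"` or `"ply"`.
#' @param binary write the binary dialect instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  format <- mesh_format(path, format)
  v <- mesh$vertices
  f <- matrix(as.integer(mesh$faces), ncol = 3)
  if (format == "stl") {
    n <- face_normals(mesh)
    if (binary) write_stl_binary(v, f, n, path) else write_stl_ascii(v, f, n, path)
  } else {
    if (binary) write_ply_binary(v, f, path) else write_ply_ascii(v, f, path)
  }
  invisible(path)
}

#' Read a surface mesh from STL or PLY
#'
#' Accepts ASCII and binary dialects of both formats. STL triangle soup is
#' welded back into an indexed mesh on exact vertex coordinates.
#'
#' @param path input file.
#' @param format `"stl"` or `"ply"`; inferred from the extension by default.
#' @return a `surface_mesh`.
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such mesh file: ", path)
  format <- mesh_format(path, format)
  out <- if (format == "stl") read_stl(path) else read_ply(path)
  structure(list(vertices = out$vertices, faces = out$faces),
            class = "surface_mesh")
}

mesh_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("stl", "ply")))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("stl", "ply"))
    stop("cannot infer mesh format from extension '", ext,
         "'; pass format = \"stl\" or \"ply\"")
  ext
}

write_stl_ascii <- function(v, f, n, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  tri <- cbind(n,
               v[f[, 1], , drop = FALSE],
               v[f[, 2], , drop = FALSE],
               v[f[, 3], , drop = FALSE])
  lines <- sprintf(
    paste0("facet normal %.9g %.9g %.9g\n outer loop\n",
           "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
           "  vertex %.9g %.9g %.9g\n endloop\nendfacet"),
    tri[, 1], tri[, 2], tri[, 3], tri[, 4], tri[, 5], tri[, 6],
    tri[, 7], tri[, 8], tri[, 9], tri[, 10], tri[, 11], tri[, 12])
  writeLines(lines, con)
  writeLines("endsolid mesh", con)
}

write_stl_binary <- function(v, f, n, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("binary STL surface mesh", width = -80))
  writeBin(header[1:80], con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  for (t in seq_len(nrow(f))) {
    writeBin(as.numeric(c(n[t, ], v[f[t, 1], ], v[f[t, 2], ], v[f[t, 3], ])),
             con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
}

read_stl <- function(path) {
  # sniff: ASCII files start with "solid" AND contain "facet" early on
  head_raw <- readBin(path, "raw", n = 512)
  is_ascii <- length(grepRaw("^\\s*solid", head_raw)) > 0 &&
    length(grepRaw("facet", head_raw, fixed = TRUE)) > 0
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  weld_triangles(tri)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  if (nrow(xyz) %% 3 != 0) stop("malformed ASCII STL: vertex count not a multiple of 3")
  xyz
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nt <- readBin(con, "integer", size = 4, endian = "little")
  xyz <- matrix(NA_real_, 3 * nt, 3)
  for (t in seq_len(nt)) {
    vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "integer", n = 1, size = 2, endian = "little")
    xyz[(t - 1) * 3 + 1:3, ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  xyz
}

weld_triangles <- function(xyz) {
  key <- paste(xyz[, 1], xyz[, 2], xyz[, 3])
  idx <- match(key, unique(key))
  v <- xyz[!duplicated(key), , drop = FALSE]
  f <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = v, faces = f)
}

write_ply_ascii <- function(v, f, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}

write_ply_binary <- function(v, f, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format binary_little_endian 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  writeBin(as.numeric(t(v)), con, size = 8, endian = "little")
  for (t in seq_len(nrow(f))) {
    writeBin(as.raw(3), con)
    writeBin(as.integer(f[t, ] - 1L), con, size = 4, endian = "little")
  }
}

read_ply <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  # locate end_header on the raw bytes (the binary body may contain nuls)
  hend <- grepRaw("end_header\n", raw, fixed = TRUE)
  if (!length(hend)) stop("malformed PLY: no end_header")
  header <- strsplit(rawToChar(raw[seq_len(hend[1] - 1)]), "\n")[[1]]
  fmt <- header[grepl("^format", header)]
  nv <- as.integer(sub("element vertex ", "", header[grepl("^element vertex", header)]))
  nf <- as.integer(sub("element face ", "", header[grepl("^element face", header)]))
  body_start <- hend[1] + nchar("end_header\n")
  if (grepl("ascii", fmt)) {
    lines <- strsplit(rawToChar(raw[body_start:length(raw)]), "\n")[[1]]
    lines <- lines[nzchar(lines)]
    vparts <- strsplit(trimws(lines[seq_len(nv)]), "\\s+")
    v <- do.call(rbind, lapply(vparts, function(p) as.numeric(p[1:3])))
    fparts <- strsplit(trimws(lines[nv + seq_len(nf)]), "\\s+")
    f <- do.call(rbind, lapply(fparts, function(p) {
      if (as.integer(p[1]) != 3) stop("only triangle PLY faces are supported")
      as.integer(p[2:4]) + 1L
    }))
  } else if (grepl("binary_little_endian", fmt)) {
    con <- rawConnection(raw[body_start:length(raw)])
    on.exit(close(con))
    v <- matrix(readBin(con, "numeric", n = 3 * nv, size = 8,
                        endian = "little"), ncol = 3, byrow = TRUE)
    f <- matrix(NA_integer_, nf, 3)
    for (t in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", n = 1))
      if (cnt != 3) stop("only triangle PLY faces are supported")
      f[t, ] <- readBin(con, "integer", n = 3, size = 4, endian = "little") + 1L
    }
  } else stop("unsupported PLY format line: ", fmt)
  list(vertices = v, faces = f)
}
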