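#' Specification for a synthetic head surface mesh
#'
#' The coverage model only needs a closed outer-head surface; a sphere or an
#' ellipsoid of head-like dimensions stands in for an anatomical model. The
#' default semi-axes 70 x 90 x 80 mm approximate an adult head.
#'
#' @param shape `"sphere"` or `"ellipsoid"`.
#' @param semi_axes length-3 numeric, semi-axis lengths in mm (a sphere uses
#'   the first value for all three).
#' @param center length-3 numeric, center in mm.
#' @param mesh_resolution target triangle edge length in mm; the subdivision
#'   level is chosen so the mean edge does not exceed it.
#' @return object of class `head_mesh_spec`.
#' @export
head_mesh_spec <- function(shape = c("ellipsoid", "sphere"),
                           semi_axes = c(70, 90, 80),
                           center = c(0, 0, 0),
                           mesh_resolution = 5) {
  shape <- match.arg(shape)
  if (shape == "sphere") semi_axes <- rep(semi_axes[1], 3)
  if (length(semi_axes) != 3 || any(!is.finite(semi_axes)) ||
      any(semi_axes <= 0))
    stop("semi_axes must be three positive finite lengths (mm)")
  if (length(center) != 3 || any(!is.finite(center)))
    stop("center must be a finite 3-vector (mm)")
  if (!is.finite(mesh_resolution) || mesh_resolution <= 0)
    stop("mesh_resolution must be a positive edge length (mm)")
  structure(list(shape = shape, semi_axes = as.numeric(semi_axes),
                 center = as.numeric(center),
                 mesh_resolution = as.numeric(mesh_resolution)),
            class = "head_mesh_spec")
}

#' Generate a watertight head-like surface mesh
#'
#' Deterministically triangulates the requested sphere/ellipsoid as a
#' subdivided icosahedron scaled by the semi-axes, so the result is closed,
#' consistently outward-oriented, and identical for identical specs.
#'
#' @param spec a [head_mesh_spec()].
#' @return object of class `surface_mesh`: list with `vertices` (n x 3 mm)
#'   and `faces` (m x 3 integer, 1-based, outward counter-clockwise).
#' @export
gen_head_mesh <- function(spec = head_mesh_spec()) {
  if (!inherits(spec, "head_mesh_spec")) spec <- do.call(head_mesh_spec, spec)
  # mean icosahedron edge on the unit sphere is ~1.0515; halves per level
  edge0 <- 1.0514622 * max(spec$semi_axes)
  level <- max(0L, ceiling(log2(edge0 / spec$mesh_resolution)))
  level <- min(level, 6L)
  ico <- icosphere(level)
  v <- sweep(ico$vertices, 2, spec$semi_axes, `*`)
  v <- sweep(v, 2, spec$center, `+`)
  structure(list(vertices = v, faces = ico$faces,
                 spec = spec, subdivision_level = level),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("bounding box (mm): [%.1f, %.1f] x [%.1f, %.1f] x [%.1f, %.1f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Enclosed volume of a closed mesh
#'
#' Signed tetrahedron sum (divergence theorem); positive for outward-oriented
#' closed surfaces.
#'
#' @param mesh a `surface_mesh` (or list with `vertices`/`faces`).
#' @return volume in the cube of the vertex unit (mm^3 for mm meshes).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Volume centroid of a closed mesh
#' @param mesh a `surface_mesh`.
#' @return length-3 numeric, same units as the vertices.
#' @export
mesh_centroid <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  w <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
       a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
       a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  ctr <- colSums((a + b + c_) / 4 * w) / sum(w)
  as.numeric(ctr)
}

#' Watertightness and orientation check
#'
#' A closed, consistently oriented triangle mesh has every undirected edge
#' shared by exactly two faces, traversed once in each direction.
#'
#' @param mesh a `surface_mesh`.
#' @return `TRUE`/`FALSE`; attribute `"why"` names the defect on failure.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]) # directed half-edges
  key <- paste(he[, 1], he[, 2])
  if (anyDuplicated(key)) {
    return(structure(FALSE, why = "duplicated directed edge (inconsistent orientation or non-manifold)"))
  }
  rkey <- paste(he[, 2], he[, 1])
  if (!all(rkey %in% key)) {
    return(structure(FALSE, why = "boundary edge (surface not closed)"))
  }
  TRUE
}

# mean edge length, mm
mesh_mean_edge <- function(mesh) {
  f <- mesh$faces; v <- mesh$vertices
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  mean(sqrt(rowSums((v[e[, 1], ] - v[e[, 2], ])^2)))
}

# smooth per-vertex normals: area-weighted average of incident face normals
vertex_normals <- function(mesh) {
  f <- mesh$faces; v <- mesh$vertices
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) # area-weighted already
  vn <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    for (c_ in 1:3) {
      acc <- tapply(fn[, c_], f[, k], sum)
      idx <- as.integer(names(acc))
      vn[idx, c_] <- vn[idx, c_] + acc
    }
  }
  vn / sqrt(rowSums(vn^2))
}

# outward unit normals per face (assumes CCW orientation)
face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / sqrt(rowSums(n^2))
}

#' Point containment by ray parity
#'
#' Tests whether points lie strictly inside a closed mesh (ray-crossing
#' parity along +x).
#'
#' @param points n x 3 matrix, same units as the mesh.
#' @param mesh a `surface_mesh`.
#' @return logical vector of length n.
#' @export
points_in_mesh <- function(points, mesh) {
  points <- as_point_matrix(points)
  wt <- mesh_is_watertight(mesh)
  if (!isTRUE(wt)) stop("mesh is not watertight: ", attr(wt, "why"))
  points_inside_cpp(points, mesh$vertices,
                    matrix(as.integer(mesh$faces), ncol = 3))
}

as_point_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3) stop("points must be n x 3")
  points
}
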