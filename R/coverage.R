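#' Voxelize the interior of a closed mesh
#'
#' Discretizes the volume enclosed by a watertight mesh as a rectilinear grid
#' (voxel centers at `origin + (index + 0.5) * spacing`, 0-based indices) and
#' marks centers strictly inside the surface by ray-crossing parity. The grid
#' tightly bounds the mesh plus a one-voxel margin.
#'
#' @param mesh a watertight `surface_mesh` (mm).
#' @param spacing voxel edge length in mm (default 1, the mapping resolution).
#' @return object of class `voxel_grid`: `origin` (mm), `spacing` (mm),
#'   `dims` (integer 3-vector), `inside_mask` (logical nx x ny x nz array).
#' @export
voxelize <- function(mesh, spacing = 1) {
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be > 0 (mm)")
  wt <- mesh_is_watertight(mesh)
  if (!isTRUE(wt)) stop("mesh is not watertight: ", attr(wt, "why"))
  bb <- apply(mesh$vertices, 2, range)
  origin <- bb[1, ] - spacing          # one-voxel margin
  dims <- as.integer(ceiling((bb[2, ] - origin) / spacing) + 1L)
  mask <- voxel_mask_cpp(mesh$vertices,
                         matrix(as.integer(mesh$faces), ncol = 3),
                         origin, spacing, dims)
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = dims,
                 inside_mask = array(mask, dim = dims)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d at %.3g mm, %d inside voxels\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              sum(x$inside_mask)))
  invisible(x)
}

#' Coordinates of voxel centers
#'
#' @param grid a `voxel_grid`.
#' @param inside_only return only centers flagged inside the mesh.
#' @return n x 3 matrix in mm.
#' @export
voxel_centers <- function(grid, inside_only = TRUE) {
  idx <- if (inside_only) which(grid$inside_mask, arr.ind = TRUE) else
    as.matrix(expand.grid(i = seq_len(grid$dims[1]),
                          j = seq_len(grid$dims[2]),
                          k = seq_len(grid$dims[3])))
  sweep((idx - 0.5) * grid$spacing, 2, grid$origin, `+`)
}

#' Place wand coil poses on the scalp surface
#'
#' Seeds `n` quasi-uniform directions (Fibonacci sphere, randomly rotated
#' under `seed`) from the mesh centroid, finds the scalp point along each
#' direction, orients the coil axis along the local outward normal, and
#' slides the coil out along that axis until the closest sampled coil point
#' (`n_rim` rim points plus the plane center) sits exactly `standoff_mm`
#' from the surface (1-D root find of the coil-to-mesh clearance).
#' Directions whose placement fails are dropped
#' with a warning, never silently substituted.
#'
#' @param mesh a watertight `surface_mesh` (mm).
#' @param n number of requested poses (default 720, the mapping configuration).
#' @param standoff_mm coil-plane-to-scalp clearance in mm (default 5,
#'   nominal housing thickness).
#' @param seed integer RNG seed for the direction-set rotation.
#' @param coil template [coil_spec()] providing radius and amp-turns.
#' @param n_rim rim sample points used for the clearance (>= 16).
#' @return object of class `wand_pose_set`: list of `coil_spec` (SI meters)
#'   plus bookkeeping (`n_requested`, `dropped`).
#' @export
place_wand_poses <- function(mesh, n = 720, standoff_mm = 5, seed = 1,
                             coil = coil_spec(), n_rim = 16) {
  stopifnot(n >= 1, n_rim >= 16, standoff_mm >= 0)
  wt <- mesh_is_watertight(mesh)
  if (!isTRUE(wt)) stop("mesh is not watertight: ", attr(wt, "why"))

  V <- mesh$vertices
  Fc <- matrix(as.integer(mesh$faces), ncol = 3)
  ctr <- mesh_centroid(mesh)
  dirs <- fibonacci_sphere(n)
  old <- .Random.seed_exists()
  set.seed(seed)
  dirs <- dirs %*% t(random_rotation())
  .Random.seed_restore(old)

  hits <- ray_mesh_cpp(ctr, dirs, V, Fc)
  vn <- vertex_normals(mesh)
  radius_mm <- coil$radius * 1000
  theta <- 2 * pi * (seq_len(n_rim) - 1) / n_rim

  poses <- vector("list", n)
  dropped <- integer(0)
  for (i in seq_len(n)) {
    t_hit <- hits[i, 1]
    if (!is.finite(t_hit)) { dropped <- c(dropped, i); next }
    q <- ctr + t_hit * dirs[i, ]
    # smooth outward normal: barycentric interpolation of vertex normals
    fidx <- mesh$faces[hits[i, 2], ]
    tri <- V[fidx, , drop = FALSE]
    bc <- barycentric_coords(q, tri)
    nv <- colSums(bc * vn[fidx, , drop = FALSE])
    nv <- nv / sqrt(sum(nv^2))
    if (sum(nv * (q - ctr)) < 0) nv <- -nv
    u <- if (abs(nv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- u - sum(u * nv) * nv; u <- u / sqrt(sum(u^2))
    w <- c(nv[2] * u[3] - nv[3] * u[2],
           nv[3] * u[1] - nv[1] * u[3],
           nv[1] * u[2] - nv[2] * u[1])
    clearance <- function(t) {
      # sample the coil disc: rim points plus the plane center (on a convex
      # scalp the center is the closest point of the coil plane)
      cpos <- rbind(
        matrix(q + t * nv, n_rim, 3, byrow = TRUE) +
          radius_mm * (outer(cos(theta), u) + outer(sin(theta), w)),
        q + t * nv)
      min(dist_to_mesh_cpp(cpos, V, Fc)) - standoff_mm
    }
    lo <- 0
    hi <- standoff_mm + 2 * radius_mm + 10
    f_lo <- clearance(lo)
    f_hi <- clearance(hi)
    expand <- 0
    while (f_hi < 0 && expand < 5) { hi <- hi * 2; f_hi <- clearance(hi); expand <- expand + 1 }
    if (f_lo >= 0) {
      t_star <- lo  # already clear at the surface (tiny coil)
    } else if (f_hi < 0) {
      dropped <- c(dropped, i); next
    } else {
      rt <- tryCatch(stats::uniroot(clearance, c(lo, hi), tol = 1e-4),
                     error = function(e) NULL)
      if (is.null(rt)) { dropped <- c(dropped, i); next }
      t_star <- rt$root
    }
    cpos_mm <- q + t_star * nv
    # non-penetration: rim must be outside the head
    rim_mm <- matrix(cpos_mm, n_rim, 3, byrow = TRUE) +
      radius_mm * (outer(cos(theta), u) + outer(sin(theta), w))
    if (any(points_inside_cpp(rim_mm, V, Fc))) { dropped <- c(dropped, i); next }
    poses[[i]] <- coil_spec(center = cpos_mm / 1000, axis = nv,
                            radius = coil$radius, amp_turns = coil$amp_turns)
  }
  poses <- poses[!vapply(poses, is.null, logical(1))]
  if (length(dropped))
    warning(length(dropped), " of ", n, " wand placements failed and were dropped")
  structure(list(poses = poses, n_requested = n, dropped = dropped,
                 standoff_mm = standoff_mm, seed = seed),
            class = "wand_pose_set")
}

#' @export
print.wand_pose_set <- function(x, ...) {
  cat(sprintf("wand_pose_set: %d poses (%d requested, %d dropped), standoff %.1f mm\n",
              length(x$poses), x$n_requested, length(x$dropped), x$standoff_mm))
  invisible(x)
}

#' Worst-case available field over implant orientation
#'
#' At a point reached by P wand poses with field vectors B_p, the field
#' available to the implant with coil normal a is |B_p . a|; the operator is
#' free to move the wand, so the available field for orientation a is
#' max_p |B_p . a|, and the worst case over all orientations is
#' W = min_{|a|=1} max_p |B_p . a|. Minimization samples icosphere
#' directions (level 4 = 2,562 by default) and refines the best direction
#' with Nelder-Mead on the tangent plane.
#'
#' @param B P x 3 matrix of field vectors (tesla) at one point, one row per
#'   wand pose.
#' @param level icosphere subdivision level for direction sampling.
#' @param refine run local Nelder-Mead refinement after sampling.
#' @return list: `value` (tesla), `orientation` (unit 3-vector attaining the
#'   minimum).
#' @export
worst_case_field <- function(B, level = 4, refine = TRUE) {
  B <- as_point_matrix(B)
  if (nrow(B) == 0) stop("B must contain at least one pose field")
  dirs <- sphere_directions(level)
  h <- available_field(B, dirs)
  i0 <- which.min(h)
  a_best <- dirs[i0, ]
  val <- h[i0]
  if (refine && val > 0) {
    # multi-start: polish from the best sampled directions in distinct
    # basins (mutual angle > 15 degrees); the minimax surface is piecewise
    # smooth with possibly narrow valleys, so a single start can stall
    ord <- order(h)
    starts <- list()
    for (i in ord) {
      a <- dirs[i, ]
      if (all(vapply(starts, function(s) abs(sum(s * a)) < cos(15 * pi / 180),
                     logical(1)))) {
        starts[[length(starts) + 1]] <- a
        if (length(starts) >= 6) break
      }
    }
    for (a0 in starts) {
      pol <- polish_minimax(B, a0)
      if (pol$value < val) { val <- pol$value; a_best <- pol$orientation }
    }
  }
  list(value = val, orientation = as.numeric(a_best))
}

# Nelder-Mead descent of max_p |B_p . a| on the tangent chart at a0
polish_minimax <- function(B, a0) {
  u <- if (abs(a0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- u - sum(u * a0) * a0; u <- u / sqrt(sum(u^2))
  w <- c(a0[2] * u[3] - a0[3] * u[2],
         a0[3] * u[1] - a0[1] * u[3],
         a0[1] * u[2] - a0[2] * u[1])
  obj <- function(xy) {
    a <- a0 + xy[1] * u + xy[2] * w
    a <- a / sqrt(sum(a^2))
    max(abs(B %*% a))
  }
  opt <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 800))
  # restart once from the found point (standard Nelder-Mead practice near
  # non-smooth minima)
  opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-12, maxit = 800))
  if (opt2$value < opt$value) opt <- opt2
  a <- a0 + opt$par[1] * u + opt$par[2] * w
  list(value = opt$value, orientation = a / sqrt(sum(a^2)))
}

#' Best-case available field (ideal orientation)
#'
#' With the implant normal aligned to the strongest pose's field,
#' M = max_p |B_p|.
#'
#' @param B P x 3 matrix of field vectors (tesla) at one point.
#' @return tesla.
#' @export
best_case_field <- function(B) {
  B <- as_point_matrix(B)
  if (nrow(B) == 0) stop("B must contain at least one pose field")
  max(sqrt(rowSums(B^2)))
}

# max_p |B_p . a| for each direction row of `dirs`
available_field <- function(B, dirs) {
  m <- abs(dirs %*% t(B))
  do.call(pmax, as.data.frame(m))
}

#' Powerability map over the head volume
#'
#' The end-to-end coverage model: voxelize the head interior, place wand
#' poses on the scalp, evaluate the coil field of every pose at every inside
#' voxel, and reduce to the worst-case (minimax over orientation) and
#' best-case available field. Voxels are classified against the powering
#' threshold: `always_powered` where W >= threshold (a measurement is
#' possible in the worst-case orientation), `unreachable` where M <
#' threshold, `orientation_dependent` between.
#'
#' @param mesh watertight head `surface_mesh` (mm).
#' @param coil_template [coil_spec()] giving radius and amp-turns.
#' @param n_poses wand poses to request (default 720).
#' @param spacing_mm voxel size (default 1).
#' @param threshold_t powering threshold in tesla RMS (default 2.8e-5).
#' @param standoff_mm wand standoff from scalp (default 5).
#' @param seed RNG seed (pose placement).
#' @param level icosphere level for orientation sampling (default 4).
#' @param chunk_size voxels per evaluation block (memory control).
#' @return object of class `coverage_map`: the grid, pose set, per-voxel `W`
#'   and `M` arrays (tesla, NA outside), `class` array (factor levels
#'   `always_powered`, `orientation_dependent`, `unreachable`), `threshold`.
#' @export
coverage_map <- function(mesh, coil_template = coil_spec(), n_poses = 720,
                         spacing_mm = 1, threshold_t = 2.8e-5,
                         standoff_mm = 5, seed = 1, level = 4,
                         chunk_size = 40000L) {
  grid <- voxelize(mesh, spacing_mm)
  pose_set <- place_wand_poses(mesh, n = n_poses, standoff_mm = standoff_mm,
                               seed = seed, coil = coil_template)
  poses <- pose_set$poses
  if (length(poses) == 0) stop("no feasible wand poses")
  centers_m <- voxel_centers(grid, inside_only = TRUE) / 1000
  n_in <- nrow(centers_m)
  P <- length(poses)
  dirs <- sphere_directions(level)
  coarse <- sphere_directions(1) # 42 directions for the pruning bound

  W <- numeric(n_in); M <- numeric(n_in)
  start <- 1L
  while (start <= n_in) {
    end <- min(n_in, start + chunk_size - 1L)
    pts <- centers_m[start:end, , drop = FALSE]
    nc <- nrow(pts)
    Barr <- array(0, dim = c(nc, P, 3))
    for (p in seq_len(P)) Barr[, p, ] <- field_batch(poses[[p]], pts)
    res <- minimax_field_cpp(as.numeric(Barr), nc, P, dirs, coarse)
    W[start:end] <- res[, 1]
    M[start:end] <- res[, 2]
    start <- end + 1L
  }

  Wa <- array(NA_real_, grid$dims); Wa[grid$inside_mask] <- W
  Ma <- array(NA_real_, grid$dims); Ma[grid$inside_mask] <- M
  cls <- classify_coverage(Wa, Ma, threshold_t)
  structure(list(grid = grid, pose_set = pose_set, W = Wa, M = Ma,
                 class = cls, threshold = threshold_t,
                 coil_template = coil_template, level = level, seed = seed),
            class = "coverage_map")
}

# classification per the map invariants: always_powered <=> W >= threshold,
# unreachable <=> M < threshold
classify_coverage <- function(W, M, threshold) {
  cls <- array(NA_integer_, dim = dim(W))
  in_mask <- !is.na(W)
  cls[in_mask] <- 1L                                   # orientation_dependent
  cls[in_mask & W >= threshold] <- 0L                  # always_powered
  cls[in_mask & M < threshold] <- 2L                   # unreachable
  attr(cls, "levels") <- c("always_powered", "orientation_dependent",
                           "unreachable")
  cls
}

#' @export
print.coverage_map <- function(x, ...) {
  n_in <- sum(x$grid$inside_mask)
  tab <- tabulate(x$class[!is.na(x$class)] + 1L, 3)
  cat(sprintf("coverage_map: %d inside voxels at %.3g mm, %d poses, threshold %.3g T\n",
              n_in, x$grid$spacing, length(x$pose_set$poses), x$threshold))
  cat(sprintf("  always_powered        %d (%.1f%%)\n", tab[1], 100 * tab[1] / n_in))
  cat(sprintf("  orientation_dependent %d (%.1f%%)\n", tab[2], 100 * tab[2] / n_in))
  cat(sprintf("  unreachable           %d (%.1f%%)\n", tab[3], 100 * tab[3] / n_in))
  invisible(x)
}

#' Export a 2-D slice of the powerability classification
#'
#' Cuts the class volume on a sagittal (fixed x), coronal (fixed y) or axial
#' (fixed z) plane and writes a CSV of class labels (plus a PNG rendering
#' unless `png = FALSE`).
#'
#' @param map a `coverage_map`.
#' @param plane `"sagittal"`, `"coronal"` or `"axial"`.
#' @param index 1-based voxel index along the fixed axis; defaults to the
#'   middle slice.
#' @param path_prefix if non-NULL, writes `<prefix>.csv` (and `<prefix>.png`
#'   when `png = TRUE`).
#' @param png also write the PNG rendering (set FALSE for text-only runs).
#' @return the slice as a character matrix of class labels (invisibly if
#'   written to disk).
#' @export
export_slice <- function(map, plane = c("sagittal", "coronal", "axial"),
                         index = NULL, path_prefix = NULL, png = TRUE) {
  plane <- match.arg(plane)
  ax <- switch(plane, sagittal = 1L, coronal = 2L, axial = 3L)
  if (is.null(index)) index <- ceiling(map$grid$dims[ax] / 2)
  if (index < 1 || index > map$grid$dims[ax])
    stop("slice index out of range [1, ", map$grid$dims[ax], "]")
  sl <- switch(ax,
               map$class[index, , ],
               map$class[, index, ],
               map$class[, , index])
  lv <- c("always_powered", "orientation_dependent", "unreachable")
  lab <- matrix(ifelse(is.na(sl), "outside", lv[sl + 1L]), nrow = nrow(sl))
  if (!is.null(path_prefix)) {
    utils::write.table(lab, paste0(path_prefix, ".csv"), sep = ",",
                       row.names = FALSE, col.names = FALSE)
    if (isTRUE(png)) {
      # 0 always (light blue), 1 dependent (dark blue), 2 unreachable (grey)
      cols <- c(outside = "#FFFFFF", always_powered = "#9FD8EF",
                orientation_dependent = "#1F4E8C", unreachable = "#BBBBBB")
      rgbv <- grDevices::col2rgb(cols[t(lab)[rev(seq_len(ncol(lab))), , drop = FALSE]]) / 255
      img <- array(t(rgbv), dim = c(ncol(lab), nrow(lab), 3))
      png::writePNG(img, paste0(path_prefix, ".png"))
    }
    return(invisible(lab))
  }
  lab
}

#' Read back a slice CSV written by [export_slice()]
#' @param path the `.csv` file.
#' @return character matrix of class labels.
#' @export
read_slice_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", stringsAsFactors = FALSE))
}

# barycentric coordinates of a (near-)in-plane point w.r.t. a 3-D triangle
barycentric_coords <- function(p, tri) {
  e1 <- tri[2, ] - tri[1, ]; e2 <- tri[3, ] - tri[1, ]; ap <- p - tri[1, ]
  d11 <- sum(e1 * e1); d12 <- sum(e1 * e2); d22 <- sum(e2 * e2)
  r1 <- sum(ap * e1); r2 <- sum(ap * e2)
  den <- d11 * d22 - d12^2
  u <- (d22 * r1 - d12 * r2) / den
  v <- (d11 * r2 - d12 * r1) / den
  c(1 - u - v, u, v)
}

# tiny helpers to save/restore the global RNG state around seeded sections
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
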