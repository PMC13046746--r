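#' Circular wand-coil specification
#'
#' The powering wand is modelled as an ideal circular filament carrying a
#' lumped amp-turn current: the field source for the coverage model. Defaults
#' follow the hardware: 15 cm diameter, 11 amp-turns RMS (the wand maximum),
#' so computed fields are RMS values directly comparable to the 28 uT_RMS
#' powering threshold.
#'
#' @param center coil center, meters (length 3).
#' @param axis coil-plane normal; normalized internally, must be non-zero.
#' @param radius coil radius in meters (default 0.075).
#' @param amp_turns RMS amp-turns (current x turns; default 11).
#' @return object of class `coil_spec`.
#' @export
coil_spec <- function(center = c(0, 0, 0), axis = c(0, 0, 1),
                      radius = 0.075, amp_turns = 11) {
  if (length(center) != 3 || any(!is.finite(center)))
    stop("center must be a finite 3-vector (m)")
  if (length(axis) != 3 || any(!is.finite(axis)) || sum(axis^2) == 0)
    stop("axis must be a non-zero 3-vector")
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0 (m)")
  if (!is.finite(amp_turns) || amp_turns < 0) stop("amp_turns must be >= 0")
  structure(list(center = as.numeric(center),
                 axis = as.numeric(axis) / sqrt(sum(axis^2)),
                 radius = as.numeric(radius),
                 amp_turns = as.numeric(amp_turns)),
            class = "coil_spec")
}

#' @export
print.coil_spec <- function(x, ...) {
  cat(sprintf(
    "coil_spec: radius %.3f m, %.2f AT_RMS, center (%.3f, %.3f, %.3f) m, axis (%.3f, %.3f, %.3f)\n",
    x$radius, x$amp_turns, x$center[1], x$center[2], x$center[3],
    x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

#' Magnetic field of a circular coil at one point
#'
#' Exact magnetostatic field of the ideal circular filament, evaluated from
#' the closed-form solution in complete elliptic integrals. RMS current in,
#' RMS field out. The on-axis limit reduces to B = mu0 N I R^2 /
#' (2 (R^2 + z^2)^(3/2)), i.e. mu0 N I / (2 R) at the coil center.
#'
#' @param coil a [coil_spec()].
#' @param point length-3 numeric, meters. Must be farther than
#'   `min_filament_dist` from the filament circle.
#' @param min_filament_dist singularity guard distance in meters.
#' @return length-3 numeric, tesla (RMS).
#' @export
coil_field <- function(coil, point, min_filament_dist = 1e-6) {
  stopifnot(inherits(coil, "coil_spec"))
  pt <- as_point_matrix(point)
  if (nrow(pt) != 1) stop("coil_field takes a single point; use field_batch")
  drop(coil_field_cpp(pt, coil$center, coil$axis, coil$radius,
                      coil$amp_turns, min_filament_dist))
}

#' Magnetic field of a circular coil over many points
#'
#' Vectorized, elementwise identical to [coil_field()]; evaluates the
#' elliptic-integral closed form in compiled code so million-point voxel
#' grids are tractable.
#'
#' @param coil a [coil_spec()].
#' @param points n x 3 matrix, meters.
#' @param min_filament_dist singularity guard distance in meters.
#' @return n x 3 matrix of B vectors, tesla (RMS).
#' @export
field_batch <- function(coil, points, min_filament_dist = 1e-6) {
  stopifnot(inherits(coil, "coil_spec"))
  points <- as_point_matrix(points)
  coil_field_cpp(points, coil$center, coil$axis, coil$radius,
                 coil$amp_turns, min_filament_dist)
}

# vacuum permeability, T m / A
MU0 <- 4e-7 * pi
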