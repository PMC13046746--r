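#' Subdivided icosahedron on the unit sphere
#'
#' Builds a geodesic sphere by recursive 4-to-1 subdivision of an
#' icosahedron, projecting every new vertex back onto the unit sphere.
#' Level `L` has `20 * 4^L` faces and `10 * 4^L + 2` vertices; level 4
#' gives the 2,562 quasi-uniform directions used for orientation sampling.
#'
#' @param level non-negative integer subdivision level.
#' @return list with `vertices` (n x 3, unit norm) and `faces`
#'   (m x 3 integer, 1-based, counter-clockwise seen from outside).
#' @export
icosphere <- function(level = 4) {
  stopifnot(is.numeric(level), length(level) == 1, level >= 0)
  level <- as.integer(level)

  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )

  for (l in seq_len(level)) {
    nv <- nrow(v)
    midcache <- new.env(hash = TRUE, parent = emptyenv())
    newv <- list(v)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- midcache[[key]]
      if (!is.null(idx)) return(idx)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1
      newv[[length(newv) + 1]] <<- m
      midcache[[key]] <- nv
      nv
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[(t - 1) * 4 + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, newv)
    f <- newf
  }
  list(vertices = v, faces = f)
}

#' Quasi-uniform unit-sphere directions
#'
#' Vertices of an icosphere, used to sample candidate implant orientations
#' when minimizing the available field over orientation.
#'
#' @param level icosphere subdivision level (level 4 = 2,562 directions).
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_directions <- function(level = 4) icosphere(level)$vertices

# Fibonacci (golden-angle) point set on the unit sphere; deterministic,
# used for seeding wand placement directions.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(th), r * sin(th), z)
}

# Random rotation matrix from a seed-driven RNG stream (uniform via QR).
random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
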