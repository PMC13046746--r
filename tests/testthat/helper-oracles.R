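# Independent oracles used by the tests. These deliberately avoid the
# package's own algorithms: the minimax oracle enumerates active sets, the
# field oracle integrates Biot-Savart numerically, and the containment oracle
# uses generalized winding numbers. Keep them simple and slow.

# Exact minimax of h(a) = max_p |b_p . a| over unit vectors a, by enumerating
# candidate stationary directions: active sets of size 1 (pose directions),
# size 2 (equal-magnitude great circles and mutual perpendiculars), and size 3
# (solutions of M a = (1,1,1) over sign patterns). The minimum of a piecewise
# linear function of a on the sphere is attained at one of these candidates.
oracle_minimax <- function(B) {
  P <- nrow(B)
  cand <- list()
  add <- function(a) {
    n <- sqrt(sum(a^2))
    if (is.finite(n) && n > 1e-12) cand[[length(cand) + 1]] <<- a / n
  }
  for (p in seq_len(P)) add(B[p, ])
  if (P >= 2) {
    for (i in 1:(P - 1)) for (j in (i + 1):P) {
      add(pracma::cross(B[i, ], B[j, ]))
      for (s in c(1, -1)) {
        d <- B[i, ] - s * B[j, ]
        nd <- sqrt(sum(d^2))
        if (nd > 1e-12) {
          u <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
          u <- u - sum(u * d) / nd^2 * d
          u <- u / sqrt(sum(u^2))
          w <- pracma::cross(d / nd, u)
          bu <- sum(B[i, ] * u); bw <- sum(B[i, ] * w)
          if (bu^2 + bw^2 > 1e-30) {
            t0 <- atan2(bw, bu)
            for (t in t0 + c(0, 0.5, 1, 1.5) * pi) add(cos(t) * u + sin(t) * w)
          }
        }
      }
    }
  }
  if (P >= 3) {
    cmb <- utils::combn(P, 3)
    for (k in seq_len(ncol(cmb))) {
      M0 <- B[cmb[, k], ]
      for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
        a <- tryCatch(solve(M0 * c(1, s2, s3), c(1, 1, 1)),
                      error = function(e) NULL)
        if (!is.null(a)) add(a)
      }
    }
  }
  min(vapply(cand, function(a) max(abs(B %*% a)), numeric(1)))
}

# Brute-force direction-sampling minimax with a single Nelder-Mead polish from
# its own best sampled direction (tangent-plane chart). Independent of the
# package's icosphere/multi-start implementation.
oracle_minimax_brute <- function(B, n_dirs = 1e5) {
  i <- seq_len(n_dirs) - 0.5
  phi <- acos(1 - 2 * i / n_dirs)
  theta <- pi * (1 + sqrt(5)) * i
  dirs <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  h <- apply(abs(B %*% t(dirs)), 2, max)
  a0 <- dirs[which.min(h), ]
  u <- if (abs(a0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- u - sum(u * a0) * a0; u <- u / sqrt(sum(u^2))
  w <- pracma::cross(a0, u)
  f <- function(cc) {
    a <- a0 + cc[1] * u + cc[2] * w
    max(abs(B %*% (a / sqrt(sum(a^2)))))
  }
  opt <- stats::optim(c(0, 0), f, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 500))
  min(min(h), opt$value)
}

# Biot-Savart field of a circular loop by adaptive quadrature over the loop
# angle, per Cartesian component. amp_turns in ampere-turns, lengths in
# meters, field in tesla.
oracle_loop_field <- function(point, center, axis, radius, amp_turns) {
  axis <- axis / sqrt(sum(axis^2))
  u <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- u - sum(u * axis) * axis; u <- u / sqrt(sum(u^2))
  w <- pracma::cross(axis, u)
  mu0 <- 4e-7 * pi
  comp <- function(k) {
    integrand <- function(t) {
      vapply(t, function(ti) {
        pos <- center + radius * (cos(ti) * u + sin(ti) * w)
        dl <- radius * (-sin(ti) * u + cos(ti) * w)
        r <- point - pos
        rn <- sqrt(sum(r^2))
        pracma::cross(dl, r)[k] / rn^3
      }, numeric(1))
    }
    stats::integrate(integrand, 0, 2 * pi, rel.tol = 1e-10,
                     abs.tol = 1e-15, subdivisions = 400L,
                     stop.on.error = FALSE)$value
  }
  mu0 * amp_turns / (4 * pi) * vapply(1:3, comp, numeric(1))
}

# Point-in-mesh oracle via the generalized winding number (sum of signed
# solid angles of the triangles, van Oosterom & Strackee).
oracle_point_in_mesh <- function(point, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  total <- 0
  for (k in seq_len(nrow(f))) {
    a <- v[f[k, 1], ] - point
    b <- v[f[k, 2], ] - point
    c_ <- v[f[k, 3], ] - point
    la <- sqrt(sum(a^2)); lb <- sqrt(sum(b^2)); lc <- sqrt(sum(c_^2))
    num <- sum(a * pracma::cross(b, c_))
    den <- la * lb * lc + sum(a * b) * lc + sum(a * c_) * lb + sum(b * c_) * la
    total <- total + 2 * atan2(num, den)
  }
  abs(total / (4 * pi)) > 0.5
}

# Random unit vector, reproducible under the caller's seed.
runif_dir <- function(n = 1) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}
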