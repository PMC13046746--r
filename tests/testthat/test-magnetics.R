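MU0 <- 4e-7 * pi

test_that("coil center field matches mu0 N I / (2 R)", {
  coil <- coil_spec()
  b <- coil_field(coil, c(0, 0, 0))
  expect_equal(b[3], MU0 * 11 / (2 * 0.075), tolerance = 1e-14)
  expect_equal(b[1:2], c(0, 0))
})

test_that("on-axis field matches the textbook closed form", {
  coil <- coil_spec(radius = 0.06, amp_turns = 7)
  for (z in c(-0.2, -0.03, 0.01, 0.1)) {
    b <- coil_field(coil, c(0, 0, z))
    expect_equal(b[3], MU0 * 7 * 0.06^2 / (2 * (0.06^2 + z^2)^1.5),
                 tolerance = 1e-13)
    expect_equal(b[1:2], c(0, 0))
  }
})

test_that("closed form matches Biot-Savart quadrature at random points", {
  coil <- coil_spec(center = c(0.02, -0.01, 0.05), axis = c(1, 2, -1),
                    radius = 0.075, amp_turns = 11)
  set.seed(3)
  pts <- matrix(runif(30 * 3, -0.15, 0.15), ncol = 3)
  for (i in seq_len(nrow(pts))) {
    b_cf <- coil_field(coil, pts[i, ])
    b_or <- oracle_loop_field(pts[i, ], coil$center, coil$axis,
                              coil$radius, coil$amp_turns)
    expect_equal(b_cf, b_or, tolerance = 1e-9)
  }
})

test_that("field is linear in amp-turns", {
  p <- c(0.03, 0.04, 0.02)
  b1 <- coil_field(coil_spec(amp_turns = 1), p)
  b11 <- coil_field(coil_spec(amp_turns = 11), p)
  expect_equal(b11, 11 * b1, tolerance = 1e-14)
  expect_equal(coil_field(coil_spec(amp_turns = 0), p), c(0, 0, 0))
})

test_that("field respects the coil's mirror symmetry", {
  coil <- coil_spec()
  p <- c(0.03, -0.02, 0.04)
  b <- coil_field(coil, p)
  bm <- coil_field(coil, c(p[1], p[2], -p[3]))  # reflect through coil plane
  expect_equal(bm[1:2], -b[1:2], tolerance = 1e-13)
  expect_equal(bm[3], b[3], tolerance = 1e-13)
  br <- coil_field(coil, c(-p[1], -p[2], p[3])) # rotate pi about the axis
  expect_equal(br[1:2], -b[1:2], tolerance = 1e-13)
  expect_equal(br[3], b[3], tolerance = 1e-13)
})

test_that("field is divergence-free away from the filament", {
  coil <- coil_spec()
  h <- 3e-5
  set.seed(5)
  for (rep in 1:10) {
    p <- runif(3, -0.12, 0.12)
    if (abs(sqrt(p[1]^2 + p[2]^2) - coil$radius) < 0.01 && abs(p[3]) < 0.01)
      next  # keep finite differences away from the singularity
    div <- 0
    for (k in 1:3) {
      e <- c(0, 0, 0); e[k] <- h
      div <- div + (coil_field(coil, p + e)[k] - coil_field(coil, p - e)[k]) /
        (2 * h)
    }
    scale <- sqrt(sum(coil_field(coil, p)^2)) / (2 * h)
    expect_lt(abs(div) / scale, 1e-6)
  }
})

test_that("far field approaches the magnetic dipole law", {
  coil <- coil_spec(radius = 0.05, amp_turns = 11)
  m <- coil$amp_turns * pi * coil$radius^2
  # the exact on-axis field deviates from the dipole by ~1.5 (R/r)^2 terms;
  # test in the regime where that correction is well below 1%
  for (r in c(20, 40) * coil$radius) {
    b_ax <- coil_field(coil, c(0, 0, r))[3]
    expect_equal(b_ax, MU0 * 2 * m / (4 * pi * r^3),
                 tolerance = 4 * (coil$radius / r)^2)
    b_eq <- coil_field(coil, c(r, 0, 0))[3]
    expect_equal(b_eq, -MU0 * m / (4 * pi * r^3),
                 tolerance = 4 * (coil$radius / r)^2)
  }
})

test_that("points on the filament are rejected, not silently evaluated", {
  coil <- coil_spec()
  expect_error(coil_field(coil, c(coil$radius, 0, 0)), "filament")
})

test_that("field_batch equals row-wise coil_field and is permutation-equivariant", {
  coil <- coil_spec(axis = c(1, 1, 1))
  set.seed(9)
  pts <- matrix(runif(25 * 3, -0.1, 0.1), ncol = 3)
  Bb <- field_batch(coil, pts)
  for (i in seq_len(nrow(pts)))
    expect_equal(Bb[i, ], coil_field(coil, pts[i, ]), tolerance = 1e-15)
  perm <- sample(nrow(pts))
  expect_equal(field_batch(coil, pts[perm, ]), Bb[perm, ])
})

test_that("field_batch evaluates 1e5 points quickly", {
  coil <- coil_spec()
  pts <- matrix(runif(1e5 * 3, -0.1, 0.1), ncol = 3)
  elapsed <- system.time(field_batch(coil, pts))["elapsed"]
  expect_lt(elapsed, 5)
})

test_that("coil_spec validates inputs", {
  expect_error(coil_spec(radius = -1), "radius")
  expect_error(coil_spec(axis = c(0, 0, 0)), "axis")
  expect_error(coil_spec(amp_turns = -2), "amp_turns")
  expect_error(coil_spec(center = c(1, 2)), "center")
})
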