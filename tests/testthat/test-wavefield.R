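make_map <- function(values, dx = 0.1e-3, fr = 10e3, x0 = NULL) {
  x <- (seq_len(nrow(values)) - 1) * dx
  if (is.null(x0)) x0 <- mean(range(x))
  spatio_temporal_map(values, x, fr, x0)
}

plane_wave <- function(np, nt, f0_bins, k0_bins, direction = "right") {
  s <- if (direction == "right") -1 else 1
  outer(seq_len(np) - 1, seq_len(nt) - 1, function(p, q)
    sin(2 * pi * (f0_bins * q / nt + s * k0_bins * p / np)))
}

test_that("depth averaging matches hand-computable windows", {
  geo <- small_oce_geometry()
  nz <- length(geo$depth_positions); nx <- length(geo$lateral_positions)
  # constant in depth: map equals any single-depth slice
  base <- matrix(rnorm(nx * 6), nx, 6)
  u <- array(0, dim = c(nz, nx, 6))
  for (iz in seq_len(nz)) u[iz, , ] <- base
  m <- depth_average(displacement_field(u, geo))
  expect_equal(m$values, base, tolerance = 1e-12)
  # two depths with values v and -v cancel
  geo2 <- oce_geometry(n_lateral = 21, n_depth = 2, depth_span = 100e-6)
  v2 <- array(0, dim = c(2, 21, 4))
  v2[1, , ] <- 1e-8; v2[2, , ] <- -1e-8
  expect_equal(max(abs(depth_average(displacement_field(v2, geo2))$values)), 0)
  # linear in depth over 5 bins: mean equals the middle bin
  geo5 <- oce_geometry(n_lateral = 21, n_depth = 5, depth_span = 400e-6)
  v5 <- array(rep(1:5 * 1e-9, times = 21 * 4), dim = c(5, 21, 4))
  expect_equal(depth_average(displacement_field(v5, geo5))$values,
               matrix(3e-9, 21, 4), tolerance = 1e-12)
})

test_that("depth averaging is invariant to reordering the included bins", {
  geo <- small_oce_geometry()
  nz <- length(geo$depth_positions); nx <- length(geo$lateral_positions)
  u <- array(rnorm(nz * nx * 5), dim = c(nz, nx, 5))
  m1 <- depth_average(displacement_field(u, geo))
  keep <- which(geo$depth_positions <= min(geo$depth_positions) + 400e-6 + 1e-12)
  perm <- sample(keep)
  u2 <- u; u2[keep, , ] <- u[perm, , ]
  m2 <- depth_average(displacement_field(u2, geo))
  expect_equal(m1$values, m2$values, tolerance = 1e-12)
})

test_that("empty depth window is rejected", {
  geo <- small_oce_geometry()
  nz <- length(geo$depth_positions); nx <- length(geo$lateral_positions)
  f <- displacement_field(array(0, dim = c(nz, nx, 4)), geo)
  expect_error(depth_average(f, z_start = 1), "empty depth window")
})

test_that("directional filter isolates single-direction plane waves", {
  v <- plane_wave(32, 64, f0_bins = 6, k0_bins = 4, direction = "right")
  m <- make_map(v)
  e_in <- sum(v^2)
  e_r <- sum(directional_filter(m, "right", pad = 1)$values^2)
  e_l <- sum(directional_filter(m, "left", pad = 1)$values^2)
  expect_gt(e_r / e_in, 0.95)
  expect_lt(e_l / e_in, 0.05)
})

test_that("equal left/right superposition splits energy evenly", {
  v <- plane_wave(32, 64, 6, 4, "right") + plane_wave(32, 64, 9, 5, "left")
  m <- make_map(v)
  e_in <- sum(v^2)
  e_r <- sum(directional_filter(m, "right", pad = 1)$values^2)
  e_l <- sum(directional_filter(m, "left", pad = 1)$values^2)
  expect_equal(e_r / e_in, 0.5, tolerance = 0.1)
  expect_equal(e_l / e_in, 0.5, tolerance = 0.1)
})

test_that("a constant map has no directional content", {
  m <- make_map(matrix(3.7, 16, 16))
  out <- directional_filter(m, "right", pad = 1)
  expect_lt(max(abs(out$values)), 1e-10)
})

test_that("left and right outputs partition the input up to a constant", {
  withr::with_seed(12, v <- matrix(rnorm(32 * 32), 32, 32))
  m <- make_map(v)
  recon <- directional_filter(m, "left")$values +
    directional_filter(m, "right")$values
  resid <- v - recon
  expect_lt(sd(resid), 1e-10)                  # difference is a pure constant
})

test_that("directional filtering requires a minimum grid", {
  expect_error(directional_filter(make_map(matrix(0, 4, 64)), "left"),
               "at least 8")
})

test_that("bilateral split mirrors a symmetric field and sizes the sides", {
  geo <- oce_geometry()                        # 7.83 mm, center excitation
  f <- make_displacement_field(geo, 2, pulse = pulse_spec(573, 573, 1e-7, 0))
  m <- depth_average(f)
  sides <- split_bilateral(m, exclusion = 0.5e-3)
  expect_equal(sides$left$lateral_positions, sides$right$lateral_positions)
  expect_equal(sides$left$values, sides$right$values, tolerance = 1e-12)
  # each side spans about (7.83/2 - 0.5) = 3.415 mm
  expect_equal(diff(range(sides$right$lateral_positions)), 3.4e-3,
               tolerance = 0.02)
  expect_error(split_bilateral(m, exclusion = 4e-3), "half-span")
})

test_that("boundary excitation yields a single-sided split with a warning", {
  v <- matrix(rnorm(20 * 10), 20, 10)
  x <- seq(0, 2e-3, length.out = 20)
  m <- spatio_temporal_map(v, x, 1e4, excitation_position = 0)
  expect_warning(sides <- split_bilateral(m, 0.2e-3), "single-sided")
  expect_null(sides$left)
  expect_false(is.null(sides$right))
})
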