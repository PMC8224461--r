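gauss_pulse <- function(t, t0, f0 = 800, sigma = 0.6e-3) {
  cos(2 * pi * f0 * (t - t0)) * exp(-(t - t0)^2 / (2 * sigma^2))
}

delayed_map <- function(speed, np = 40, nt = 200, fr = 30e3, dx = 0.1e-3,
                        x_from = 0.5e-3) {
  x <- x_from + (seq_len(np) - 1) * dx
  t <- (seq_len(nt) - 1) / fr
  v <- t(vapply(x, function(xi) gauss_pulse(t, 2e-3 + xi / speed), numeric(nt)))
  spatio_temporal_map(v, x, fr, excitation_position = 0, direction_tag = "right")
}

test_that("integer delays are recovered exactly", {
  fr <- 30e3
  t <- (0:199) / fr
  ref <- gauss_pulse(t, 2e-3)
  v <- rbind(ref, gauss_pulse(t, 2e-3 + 7 / fr), gauss_pulse(t, 2e-3 + 14 / fr))
  m <- spatio_temporal_map(v, c(1e-3, 2e-3, 3e-3), fr, 0)
  ats <- xcorr_arrival_times(m)
  expect_equal(ats$arrival_times[1], 0, tolerance = 1e-10)
  expect_equal(ats$arrival_times[2] * fr, 7, tolerance = 1e-4)
  expect_equal(ats$correlation_peaks[1], 1, tolerance = 1e-10)
})

test_that("parabolic refinement resolves fractional delays to 0.1 sample", {
  fr <- 30e3
  t <- (0:199) / fr
  ref <- gauss_pulse(t, 2e-3)
  frac <- gauss_pulse(t, 2e-3 + 2.5 / fr)
  m <- spatio_temporal_map(rbind(ref, ref, frac), c(1, 2, 3) * 1e-3, fr, 0)
  ats <- xcorr_arrival_times(m)
  expect_equal(ats$arrival_times[3] * fr, 2.5, tolerance = 0.1 / 2.5)
  # and agrees with the brute-force fine-grid oracle
  oracle <- finegrid_lag_oracle(frac, ref)
  expect_lt(abs(ats$arrival_times[3] * fr - oracle), 0.1)
})

test_that("all-zero traces are dropped with a warning", {
  fr <- 30e3
  t <- (0:99) / fr
  ref <- gauss_pulse(t, 1.5e-3)
  v <- rbind(ref, 0 * ref, gauss_pulse(t, 1.5e-3 + 3 / fr))
  m <- spatio_temporal_map(v, c(1, 2, 3) * 1e-3, fr, 0)
  expect_warning(ats <- xcorr_arrival_times(m), "all-zero")
  expect_length(ats$distances, 2)
})

test_that("residual-weighted fit is exact on perfect lines", {
  x <- seq(1e-3, 4e-3, length.out = 12)
  fit <- residual_weighted_fit(list(distances = x, arrival_times = x / 3))
  expect_equal(fit$slope, 1 / 3, tolerance = 1e-12)
  expect_true(all(fit$weights == fit$weights[1]))
  expect_true(fit$valid)
  expect_equal(fit$r_squared, 1)
})

test_that("a gross outlier is down-weighted to near-irrelevance", {
  x <- seq(1e-3, 5e-3, length.out = 15)
  y <- x / 2.5
  resid_scale <- 2e-6
  withr::with_seed(3, y <- y + rnorm(15, sd = resid_scale))
  y_out <- y
  y_out[8] <- y[8] + 10 * resid_scale * 10
  fit <- residual_weighted_fit(list(distances = x, arrival_times = y_out))
  clean <- lm(y[-8] ~ x[-8])
  expect_equal(fit$slope, unname(coef(clean)[2]), tolerance = 0.01)
  expect_lt(fit$weights[8], 0.1 * median(fit$weights))
})

test_that("degenerate fits are rejected or flagged", {
  expect_error(residual_weighted_fit(list(distances = c(1, 2) * 1e-3,
                                          arrival_times = c(0, 1e-4))),
               "at least 3")
  x <- seq(1e-3, 3e-3, length.out = 10)
  fit <- residual_weighted_fit(list(distances = x, arrival_times = -x / 2))
  expect_false(fit$valid)                      # negative slope: no speed
})

test_that("group velocity estimation recovers a clean simulated speed", {
  geo <- oce_geometry(n_lateral = 101)
  f <- make_displacement_field(geo, 3)
  ve <- estimate_group_velocity(depth_average(f))
  expect_equal(ve$speed, 3, tolerance = 0.01)
  expect_equal(unname(ve$side_speeds["left"]), unname(ve$side_speeds["right"]),
               tolerance = 0.01)
})

test_that("asymmetric side speeds average per definition", {
  # right side at 4 m/s, left side at 2 m/s, glued at the center
  fr <- 10e3
  nt <- 160
  t <- (seq_len(nt) - 1) / fr
  x <- seq(-8e-3, 8e-3, length.out = 161)
  v <- t(vapply(x, function(xi) {
    sp <- if (xi >= 0) 4 else 2
    gauss_pulse(t, 2e-3 + abs(xi) / sp, f0 = 600, sigma = 0.8e-3)
  }, numeric(nt)))
  m <- spatio_temporal_map(v, x, fr, excitation_position = 0)
  ve <- estimate_group_velocity(m)
  expect_equal(unname(ve$side_speeds["right"]), 4, tolerance = 0.02)
  expect_equal(unname(ve$side_speeds["left"]), 2, tolerance = 0.02)
  expect_equal(ve$speed, mean(ve$side_speeds), tolerance = 1e-12)
})

test_that("speed scales inversely with time dilation and ignores amplitude", {
  m <- delayed_map(3)                          # one-sided map: left is empty
  v0 <- suppressWarnings(estimate_group_velocity(m)$speed)
  # same samples played at half the frame rate: speed halves
  m_slow <- spatio_temporal_map(m$values, m$lateral_positions,
                                m$frame_rate / 2, m$excitation_position)
  expect_equal(suppressWarnings(estimate_group_velocity(m_slow)$speed), v0 / 2,
               tolerance = 1e-10)
  m_amp <- spatio_temporal_map(5 * m$values, m$lateral_positions,
                               m$frame_rate, m$excitation_position)
  expect_equal(suppressWarnings(estimate_group_velocity(m_amp)$speed), v0,
               tolerance = 1e-12)
})
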