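test_that("OCE encode/decode round trip is exact at zero noise", {
  geo <- small_oce_geometry()
  f <- make_displacement_field(geo, 2.5)
  rec <- oce_phase_to_displacement(encode_oce_frames(f))
  expect_lt(max(abs(rec$values - f$values)), 1e-9)
})

test_that("rigid whole-sample motion is reconstructed exactly for any n", {
  for (n_refr in c(1.0, 1.33, 1.4, 1.6)) {
    geo <- oce_geometry(n_lateral = 21, n_depth = 8,
                        refractive_index_n = n_refr)
    nz <- 8; nx <- 21
    steps <- c(0, 50e-9, 120e-9, 200e-9)       # rigid: dz = ds at all depths
    u <- array(rep(steps, each = nz * nx), dim = c(nz, nx, 4))
    rec <- oce_phase_to_displacement(encode_oce_frames(displacement_field(u, geo)))
    expect_equal(rec$values, u, tolerance = 1e-6)
  }
})

test_that("surface correction algebra: ds recovered from the surface bin", {
  # hand model: uniform surface step ds with depth displacement dz = ds
  # passes through the correction unchanged (tested at observable phases,
  # scaled down from the 2*pi/655-nm worked example by 10x)
  geo <- small_oce_geometry()
  lam <- geo$wavelength_lambda0
  ds <- lam / 20                               # phase 4*pi*ds/lam = pi/5
  nz <- length(geo$depth_positions); nx <- length(geo$lateral_positions)
  u <- array(rep(c(0, ds), each = nz * nx), dim = c(nz, nx, 2))
  rec <- oce_phase_to_displacement(encode_oce_frames(displacement_field(u, geo)))
  expect_equal(rec$values[, , 2], u[, , 2], tolerance = 1e-9)
})

test_that("noise-only OCE frames are flagged low-SNR", {
  geo <- small_oce_geometry()
  nz <- length(geo$depth_positions); nx <- length(geo$lateral_positions)
  u <- array(0, dim = c(nz, nx, 20))
  fr <- encode_oce_frames(displacement_field(u, geo), noise_sd_phase = 3,
                          seed = 5)
  expect_warning(rec <- oce_phase_to_displacement(fr, unwrap = FALSE),
                 "low SNR")
  expect_true(attr(rec, "low_snr"))
})

test_that("Loupas recovers a uniform quarter-cycle step as 24.7 um per frame", {
  geo <- small_use_geometry()
  nz <- length(geo$depth_positions); nx <- length(geo$lateral_positions)
  dz <- 1540 / (8 * 7.8e6)                     # slow-time phase pi/2
  u <- array(rep(dz * 0:3, each = nz * nx), dim = c(nz, nx, 4))
  rec <- loupas_displacement(encode_us_iq(displacement_field(u, geo)))
  expect_lt(max(abs(rec$values - u)), 1e-9)
  expect_equal(rec$values[1, 1, 2], 2.467949e-5, tolerance = 1e-4)
})

test_that("Loupas is unbiased at zero motion under noise", {
  geo <- small_use_geometry()
  nz <- length(geo$depth_positions); nx <- length(geo$lateral_positions)
  u <- array(0, dim = c(nz, nx, 10))
  iq <- encode_us_iq(displacement_field(u, geo), noise_sd = 0.3, seed = 9)
  rec <- loupas_displacement(iq)
  est <- rec$values[, , 10]
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est)), 3 * se + 1e-12)
})

test_that("USE encode/decode round trip is within 1% at zero noise", {
  geo <- small_use_geometry()
  f <- make_displacement_field(geo, 2.5)
  rec <- loupas_displacement(encode_us_iq(f))
  expect_lt(max(abs(rec$values - f$values)) / max(abs(f$values)), 0.01)
})

test_that("Loupas with minimal kernels equals the Kasai lag-one estimator", {
  geo <- small_use_geometry()
  nz <- length(geo$depth_positions); nx <- length(geo$lateral_positions)
  withr::with_seed(31, {
    # smooth random motion plus noise so the equivalence is tested off the
    # easy zero-noise path
    u <- array(cumsum(rnorm(nz * nx * 8, sd = 2e-7)), dim = c(nz, nx, 8))
    iq <- encode_us_iq(displacement_field(u, geo), noise_sd = 0.2, seed = 7)
  })
  mine <- loupas_displacement(iq, depth_kernel = 1, ensemble_kernel = 2)
  oracle <- kasai_oracle(iq$values, geo$us_center_frequency, geo$sound_speed)
  expect_lt(max(abs(mine$values - oracle)) / max(abs(oracle)), 1e-10)
})

test_that("Loupas center-frequency correction follows the depth-lag phase", {
  # hand-built IQ with a residual depth carrier: phase psi per depth sample
  # shifts the estimated center frequency to f_c + psi / (2 pi T_fast), and
  # the displacement estimate scales accordingly
  geo <- small_use_geometry()
  nz <- length(geo$depth_positions); nx <- length(geo$lateral_positions)
  fc <- geo$us_center_frequency; cs <- geo$sound_speed
  t_fast <- 2 * mean(diff(geo$depth_positions)) / cs
  psi <- 0.4                                   # rad per depth sample
  phid <- 0.8                                  # slow-time phase per frame
  carrier <- exp(1i * psi * (seq_len(nz) - 1))
  vals <- array(0i, dim = c(nz, nx, 3))
  for (t in 1:3) vals[, , t] <- carrier * exp(1i * phid * (t - 1))
  rec <- loupas_displacement(complex_frame_series(vals, geo),
                             depth_kernel = 5, ensemble_kernel = 2)
  expected <- cs * phid / (4 * pi * (fc + psi / (2 * pi * t_fast)))
  expect_equal(rec$values[3, 5, 2], expected, tolerance = 1e-10)
})

test_that("both displacement estimators are linear in small motions", {
  geo <- small_oce_geometry()
  f1 <- make_displacement_field(geo, 2, pulse = pulse_spec(573, 573, 2e-8, 50))
  f2 <- displacement_field(2 * f1$values, geo)
  r1 <- oce_phase_to_displacement(encode_oce_frames(f1))
  r2 <- oce_phase_to_displacement(encode_oce_frames(f2))
  expect_equal(r2$values, 2 * r1$values, tolerance = 1e-6)

  geu <- small_use_geometry()
  g1 <- make_displacement_field(geu, 2, pulse = pulse_spec(1073, 1073, 5e-7, 50))
  g2 <- displacement_field(2 * g1$values, geu)
  l1 <- loupas_displacement(encode_us_iq(g1))
  l2 <- loupas_displacement(encode_us_iq(g2))
  expect_equal(l2$values, 2 * l1$values, tolerance = 1e-3)
})

test_that("displacement beyond the ambiguity range raises an aliasing flag", {
  geo <- small_use_geometry()
  nz <- length(geo$depth_positions); nx <- length(geo$lateral_positions)
  big <- 1540 / (4.05 * 7.8e6)                 # just under lambda/4 * 2
  u <- array(rep(c(0, big), each = nz * nx), dim = c(nz, nx, 2))
  expect_warning(rec <- loupas_displacement(encode_us_iq(displacement_field(u, geo))),
                 "ambiguity")
  expect_true(attr(rec, "aliasing_warning"))
})

test_that("modality mismatches are rejected as configuration errors", {
  geo <- small_oce_geometry()
  f <- make_displacement_field(geo, 2)
  expect_error(encode_us_iq(f), "USE")
  fr <- encode_oce_frames(f)
  expect_error(loupas_displacement(fr), "USE")
  geu <- small_use_geometry()
  fu <- make_displacement_field(geu, 2)
  expect_error(encode_oce_frames(fu), "OCE")
  expect_error(oce_phase_to_displacement(encode_us_iq(fu)), "OCE")
})
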