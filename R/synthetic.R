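#' Simulate a transient bilateral wave field
#'
#' Generates the ground-truth axial displacement field for a transient
#' surface/shear wave launched at the excitation position and propagating
#' bilaterally at a fixed group velocity:
#' `u(z, x, t) = A w(z) exp(-alpha |x - x0|) g(t - |x - x0| / speed)`,
#' where `g` is a Gaussian-enveloped cosine ([pulse_spec()]) delayed so the
#' pulse is fully contained in the time window, and `w(z)` is a smooth depth
#' profile: exponential decay from the surface (OCE surface wave) or a
#' Gaussian centered on the push focus (USE acoustic-radiation-force focal
#' region). The construction is deterministic; `seed` is accepted for
#' interface symmetry with the stochastic encoders.
#'
#' @param geometry An [acquisition_geometry()].
#' @param speed Group velocity in m/s (> 0).
#' @param pulse A [pulse_spec()]; defaults to [default_pulse()] for the
#'   geometry's modality.
#' @param depth_scale Depth-decay 1/e scale in m; defaults to 300 um (OCE
#'   surface wave) or 2 mm (USE focal region).
#' @param n_time Number of frames; by default sized to contain the slowest
#'   arrival plus the full pulse.
#' @param seed Unused (deterministic operation); kept for API uniformity.
#' @return A [displacement_field()] with `ground_truth_speed = speed`.
#' @export
make_displacement_field <- function(geometry, speed, pulse = NULL,
                                    depth_scale = NULL, n_time = NULL,
                                    seed = NULL) {
  stopifnot(inherits(geometry, "acq_geometry"))
  if (!is.finite(speed) || speed <= 0) stop("speed must be positive")
  if (is.null(pulse)) pulse <- default_pulse(geometry$modality)
  stopifnot(inherits(pulse, "pulse_spec"))
  if (is.null(depth_scale))
    depth_scale <- if (geometry$modality == "OCE") 300e-6 else 2e-3

  x <- geometry$lateral_positions
  z <- geometry$depth_positions
  d <- abs(x - geometry$excitation_position)
  sigma <- pulse_sigma(pulse)
  t0 <- 3.5 * sigma                       # lead time so the pulse onset is in-window
  if (is.null(n_time)) {
    t_end <- t0 + max(d) / speed + 3.5 * sigma
    n_time <- ceiling(t_end * geometry$frame_rate) + 1
  }
  times <- (seq_len(n_time) - 1) / geometry$frame_rate
  if (t0 + 3.5 * sigma > max(times))
    stop("pulse duration exceeds the time axis; increase n_time or frame count")

  w <- if (geometry$modality == "OCE") {
    exp(-(z - min(z)) / depth_scale)          # surface wave: decay from surface
  } else {
    # ARF focal region: smooth Gaussian profile centered on the push focus
    zref <- if (is.null(geometry$push_depth)) mean(range(z)) else geometry$push_depth
    exp(-(z - zref)^2 / (2 * depth_scale^2))
  }

  # tau[x, t] = t - delay(x) - t0; g evaluated on the lateral x time grid
  tau <- outer(-d / speed - t0, times, `+`)
  g <- cos(2 * pi * pulse$center_frequency * tau) * exp(-tau^2 / (2 * sigma^2))
  lat_t <- pulse$amplitude * exp(-pulse$attenuation_coeff * d) * g
  vals <- outer(w, lat_t)                 # [depth, lateral, time]
  dim(vals) <- c(length(z), length(x), n_time)
  displacement_field(vals, geometry, ground_truth_speed = speed)
}

#' Encode a displacement field as OCE M-B-mode frames
#'
#' Produces complex frames whose phase follows the double-pass optical path
#' model for a sample in air: `phi(z, x, t) = (4 pi / lambda0) *
#' (n * u(z, x, t) - (n - 1) * u_s(x, t))`, with `u_s` the surface
#' displacement (shallowest depth bin). Optical intensity decays
#' exponentially with depth so the surface bin carries the strongest signal.
#' Independent Gaussian phase noise of standard deviation `noise_sd_phase`
#' is added per voxel per frame.
#'
#' @param field A [displacement_field()] on an OCE geometry.
#' @param noise_sd_phase Phase noise SD in rad (>= 0).
#' @param seed Integer seed for the noise draw (reproducible).
#' @param intensity_scale Depth 1/e scale of the optical intensity (m).
#' @return A [complex_frame_series()].
#' @export
encode_oce_frames <- function(field, noise_sd_phase = 0, seed = NULL,
                              intensity_scale = 250e-6) {
  stopifnot(inherits(field, "displacement_field"))
  g <- field$geometry
  if (g$modality != "OCE") stop("encode_oce_frames requires an OCE geometry")
  if (is.null(g$wavelength_lambda0) || is.null(g$refractive_index_n))
    stop("OCE geometry must carry wavelength_lambda0 and refractive_index_n")
  u <- field$values
  d <- dim(u)
  n <- g$refractive_index_n
  us <- u[1, , , drop = FALSE]            # surface trace, broadcast over depth
  phi <- (4 * pi / g$wavelength_lambda0) *
    (n * u - (n - 1) * us[rep(1, d[1]), , , drop = FALSE])
  if (noise_sd_phase > 0) {
    noise <- withr::with_seed(seed, stats::rnorm(length(phi), sd = noise_sd_phase))
    phi <- phi + noise
  }
  z <- g$depth_positions
  amp <- exp(-(z - min(z)) / intensity_scale)
  vals <- array(amp, dim = d) * exp(1i * phi)
  complex_frame_series(vals, g)
}

#' Encode a displacement field as an ultrasound IQ ensemble
#'
#' Produces an ideal baseband IQ ensemble whose slow-time phase encodes the
#' axial displacement: `phi(z, x, t) = 4 pi f_c u(z, x, t) / c_sound`.
#' Complex white Gaussian noise is added at `noise_sd` relative to the unit
#' signal amplitude. No speckle is simulated.
#'
#' @param field A [displacement_field()] on a USE geometry.
#' @param noise_sd Complex noise SD as a fraction of signal amplitude (>= 0).
#' @param seed Integer seed for the noise draw.
#' @return A [complex_frame_series()].
#' @export
encode_us_iq <- function(field, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(field, "displacement_field"))
  g <- field$geometry
  if (g$modality != "USE") stop("encode_us_iq requires a USE geometry")
  if (is.null(g$us_center_frequency) || is.null(g$sound_speed))
    stop("USE geometry must carry us_center_frequency and sound_speed")
  phi <- 4 * pi * g$us_center_frequency * field$values / g$sound_speed
  vals <- exp(1i * phi)
  if (noise_sd > 0) {
    nz <- withr::with_seed(seed, {
      complex(real = stats::rnorm(length(phi), sd = noise_sd / sqrt(2)),
              imaginary = stats::rnorm(length(phi), sd = noise_sd / sqrt(2)))
    })
    vals <- vals + nz
  }
  complex_frame_series(vals, g)
}

#' Draw a repeated-trial speed ensemble
#'
#' Emulates removal/replacement repeatability trials: `n_trials` speeds drawn
#' as `base_speed + Normal(0, intertrial_sd)`. Non-positive draws (possible
#' at extreme SD) are redrawn with a warning.
#'
#' @param base_speed True sample speed in m/s (> 0).
#' @param n_trials Number of trials (>= 2).
#' @param intertrial_sd Between-trial SD in m/s (>= 0).
#' @param seed Integer seed (reproducible).
#' @param sample_id Label for the ensemble.
#' @return A [trial_ensemble()].
#' @export
make_trial_ensemble <- function(base_speed, n_trials = 5, intertrial_sd = 0,
                                seed = NULL, sample_id = "sample") {
  if (!is.finite(base_speed) || base_speed <= 0) stop("base_speed must be positive")
  if (n_trials < 2) stop("n_trials must be at least 2")
  if (intertrial_sd < 0) stop("intertrial_sd must be >= 0")
  speeds <- withr::with_seed(seed, {
    s <- base_speed + stats::rnorm(n_trials, sd = intertrial_sd)
    bad <- which(s <= 0)
    while (length(bad) > 0) {
      warning("non-positive trial speed drawn; redrawing")
      s[bad] <- base_speed + stats::rnorm(length(bad), sd = intertrial_sd)
      bad <- which(s <= 0)
    }
    s
  })
  trial_ensemble(sample_id, speeds)
}

#' Angle-dependent wave speed in a transversely isotropic sample
#'
#' Elliptical interpolation between the speed along the fiber axis and the
#' speed across it: `c(theta) = sqrt((c_par cos(theta))^2 +
#' (c_perp sin(theta))^2)`, monotone from `c_parallel` at 0 degrees to
#' `c_perpendicular` at 90 degrees.
#'
#' @param c_parallel Speed along the fibers (m/s, > 0).
#' @param c_perpendicular Speed across the fibers (m/s, > 0).
#' @param angle Angle(s) from the fiber axis in degrees, in `[0, 90]`.
#' @return Speed(s) in m/s.
#' @export
anisotropic_speed_profile <- function(c_parallel, c_perpendicular, angle) {
  if (c_parallel <= 0 || c_perpendicular <= 0) stop("speeds must be positive")
  if (any(angle < 0 | angle > 90)) stop("angle must lie in [0, 90] degrees")
  th <- angle * pi / 180
  sqrt((c_parallel * cos(th))^2 + (c_perpendicular * sin(th))^2)
}
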