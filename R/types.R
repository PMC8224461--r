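#' Material specification
#'
#' Bundles the mechanical constants used to convert between wave speed and
#' Young's modulus: modulus E (Pa), mass density rho (kg/m^3), and Poisson's
#' ratio nu. For a nearly incompressible soft solid (nu = 0.5) the bulk shear
#' wave speed is `sqrt(E / (3 * rho))`.
#'
#' @param young_modulus Young's modulus in Pa (> 0).
#' @param density Mass density in kg/m^3 (> 0), default 1000 (gelatin/water).
#' @param poisson_ratio Poisson's ratio in `[0, 0.5]`, default 0.5.
#' @param label Free-text sample label.
#' @return An object of class `material_spec`.
#' @export
material_spec <- function(young_modulus, density = 1000, poisson_ratio = 0.5,
                          label = "sample") {
  stopifnot(is.numeric(young_modulus), length(young_modulus) == 1)
  if (!is.finite(young_modulus) || young_modulus <= 0)
    stop("young_modulus must be positive and finite")
  if (!is.finite(density) || density <= 0)
    stop("density must be positive and finite")
  if (poisson_ratio < 0 || poisson_ratio > 0.5)
    stop("poisson_ratio must lie in [0, 0.5]")
  structure(list(young_modulus = young_modulus, density = density,
                 poisson_ratio = poisson_ratio, label = as.character(label)),
            class = "material_spec")
}

#' Shear wave speed of a material
#'
#' `c_s = sqrt(E / (3 rho))`, the incompressible-limit shear speed implied by
#' the modulus-speed relation E = 3 rho c^2.
#'
#' @param material A [material_spec()].
#' @return Shear wave speed in m/s.
#' @export
shear_speed <- function(material) {
  stopifnot(inherits(material, "material_spec"))
  sqrt(material$young_modulus / (3 * material$density))
}

#' Excitation pulse specification
#'
#' A transient excitation modeled as a Gaussian-enveloped cosine:
#' `g(t) = cos(2 pi f0 t) exp(-t^2 / (2 sigma^2))` with the envelope width
#' set so that `bandwidth` is the full width at half maximum of the amplitude
#' spectrum (`sigma = sqrt(2 log 2) / (pi * B)`).
#'
#' @param center_frequency Tone center frequency f0 in Hz (> 0).
#' @param bandwidth Spectral FWHM in Hz (> 0).
#' @param amplitude Peak displacement in m (> 0).
#' @param attenuation_coeff Lateral amplitude attenuation in 1/m (>= 0).
#' @return An object of class `pulse_spec`.
#' @export
pulse_spec <- function(center_frequency, bandwidth,
                       amplitude = 100e-9, attenuation_coeff = 0) {
  if (!is.finite(center_frequency) || center_frequency <= 0)
    stop("center_frequency must be positive")
  if (!is.finite(bandwidth) || bandwidth <= 0) stop("bandwidth must be positive")
  if (!is.finite(amplitude) || amplitude <= 0) stop("amplitude must be positive")
  if (attenuation_coeff < 0) stop("attenuation_coeff must be >= 0")
  structure(list(center_frequency = center_frequency, bandwidth = bandwidth,
                 amplitude = amplitude, attenuation_coeff = attenuation_coeff),
            class = "pulse_spec")
}

# Envelope SD (s) for a Gaussian-enveloped tone whose amplitude spectrum has
# FWHM equal to `bandwidth`.
pulse_sigma <- function(pulse) sqrt(2 * log(2)) / (pi * pulse$bandwidth)

#' Default excitation pulse for a modality
#'
#' Defaults follow the excitation bandwidths reported for the two systems:
#' roughly 573 Hz for the air-pulse OCE excitation and 1073 Hz for the
#' acoustic-radiation-force USE push, with peak displacements of 100 nm
#' (optical tracking scale) and 5 um (ARF push scale) respectively.
#'
#' @param modality `"OCE"` or `"USE"`.
#' @return A [pulse_spec()].
#' @export
default_pulse <- function(modality = c("OCE", "USE")) {
  modality <- match.arg(modality)
  if (modality == "OCE")
    pulse_spec(center_frequency = 573, bandwidth = 573,
               amplitude = 100e-9, attenuation_coeff = 50)
  else
    pulse_spec(center_frequency = 1073, bandwidth = 1073,
               amplitude = 5e-6, attenuation_coeff = 50)
}

#' Acquisition geometry
#'
#' Describes the sampling grid of an acquisition: lateral positions along the
#' measurement line, depth positions, frame rate of the slow-time axis, and
#' the lateral position of the excitation. Modality-specific optical
#' (wavelength, refractive index) or ultrasonic (center frequency, sound
#' speed, push focal depth) constants are carried along.
#'
#' @param lateral_positions Strictly monotone lateral coordinates (m).
#' @param depth_positions Strictly monotone depth coordinates (m).
#' @param frame_rate Slow-time frame rate (Hz, > 0).
#' @param excitation_position Lateral coordinate of the excitation (m),
#'   within the lateral span.
#' @param modality `"OCE"` or `"USE"`.
#' @param wavelength_lambda0 OCE central wavelength (m).
#' @param refractive_index_n OCE sample refractive index (>= 1).
#' @param us_center_frequency USE imaging/push center frequency (Hz).
#' @param sound_speed USE speed of sound (m/s).
#' @param push_depth USE push focal depth (m).
#' @return An object of class `acq_geometry`.
#' @export
acquisition_geometry <- function(lateral_positions, depth_positions, frame_rate,
                                 excitation_position,
                                 modality = c("OCE", "USE"),
                                 wavelength_lambda0 = NULL,
                                 refractive_index_n = NULL,
                                 us_center_frequency = NULL,
                                 sound_speed = NULL,
                                 push_depth = NULL) {
  modality <- match.arg(modality)
  if (length(lateral_positions) < 2 || any(diff(lateral_positions) <= 0))
    stop("lateral_positions must be strictly increasing with span > 0")
  if (length(depth_positions) < 1 || any(diff(depth_positions) <= 0))
    stop("depth_positions must be strictly increasing")
  if (!is.finite(frame_rate) || frame_rate <= 0) stop("frame_rate must be positive")
  if (excitation_position < min(lateral_positions) ||
      excitation_position > max(lateral_positions))
    stop("excitation_position must lie within the lateral span")
  if (modality == "OCE") {
    if (is.null(wavelength_lambda0) || is.null(refractive_index_n))
      stop("OCE geometry requires wavelength_lambda0 and refractive_index_n")
    if (refractive_index_n < 1) stop("refractive_index_n must be >= 1")
  } else {
    if (is.null(us_center_frequency) || is.null(sound_speed))
      stop("USE geometry requires us_center_frequency and sound_speed")
  }
  structure(list(lateral_positions = as.numeric(lateral_positions),
                 depth_positions = as.numeric(depth_positions),
                 frame_rate = frame_rate,
                 excitation_position = excitation_position,
                 modality = modality,
                 wavelength_lambda0 = wavelength_lambda0,
                 refractive_index_n = refractive_index_n,
                 us_center_frequency = us_center_frequency,
                 sound_speed = sound_speed,
                 push_depth = push_depth),
            class = "acq_geometry")
}

#' Default OCE line-scan geometry
#'
#' 251 lateral points across a 7.83 mm line, 30 kHz effective frame rate,
#' excitation at the line center, 1310 nm central wavelength. The depth axis
#' spans 0.6 mm at 15 um spacing (enough to cover a 400 um averaging window).
#'
#' @param n_lateral,lateral_span,frame_rate,n_depth,depth_span Grid controls.
#' @param wavelength_lambda0 Central wavelength (m).
#' @param refractive_index_n Sample refractive index.
#' @return An `acq_geometry` with `modality = "OCE"`.
#' @export
oce_geometry <- function(n_lateral = 251, lateral_span = 7.83e-3,
                         frame_rate = 30e3, n_depth = 40, depth_span = 0.6e-3,
                         wavelength_lambda0 = 1310e-9,
                         refractive_index_n = 1.4) {
  x <- seq(0, lateral_span, length.out = n_lateral)
  z <- seq(0, depth_span, length.out = n_depth)
  acquisition_geometry(x, z, frame_rate, excitation_position = lateral_span / 2,
                       modality = "OCE",
                       wavelength_lambda0 = wavelength_lambda0,
                       refractive_index_n = refractive_index_n)
}

#' Default USE geometry
#'
#' A 20 mm tracking line (about half the physical aperture of a 128-element
#' linear array, and wide enough that the transient pulse spans several
#' wavenumber resolution cells, which f-k directional filtering requires) at
#' 10 kHz frame rate, with the acoustic radiation force push focused 4 mm
#' deep under the line center; 7.8 MHz center frequency and 1540 m/s sound
#' speed. The depth axis brackets the focal depth (3.5-4.5 mm at 25 um
#' spacing).
#'
#' @param n_lateral,lateral_span,frame_rate,n_depth Grid controls.
#' @param push_depth Push focal depth (m).
#' @param us_center_frequency Center frequency (Hz).
#' @param sound_speed Speed of sound (m/s).
#' @return An `acq_geometry` with `modality = "USE"`.
#' @export
use_geometry <- function(n_lateral = 201, lateral_span = 20e-3,
                         frame_rate = 10e3, n_depth = 41, push_depth = 4e-3,
                         us_center_frequency = 7.8e6, sound_speed = 1540) {
  x <- seq(0, lateral_span, length.out = n_lateral)
  z <- seq(push_depth - 0.5e-3, push_depth + 0.5e-3, length.out = n_depth)
  acquisition_geometry(x, z, frame_rate, excitation_position = lateral_span / 2,
                       modality = "USE",
                       us_center_frequency = us_center_frequency,
                       sound_speed = sound_speed,
                       push_depth = push_depth)
}

#' Construct a displacement field object
#'
#' Axial displacement (m) indexed `[depth, lateral, time]` together with its
#' acquisition geometry and, when known, the ground-truth group velocity.
#'
#' @param values Numeric array `[n_depth, n_lateral, n_time]`, finite.
#' @param geometry An `acq_geometry` consistent with the array shape.
#' @param ground_truth_speed Optional known propagation speed (m/s).
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(values, geometry, ground_truth_speed = NULL) {
  stopifnot(inherits(geometry, "acq_geometry"))
  d <- dim(values)
  if (length(d) != 3) stop("values must be a 3-d array [depth, lateral, time]")
  if (d[1] != length(geometry$depth_positions) ||
      d[2] != length(geometry$lateral_positions))
    stop("array shape inconsistent with geometry axes")
  if (!all(is.finite(values))) stop("displacement values must be finite")
  structure(list(values = values, geometry = geometry,
                 ground_truth_speed = ground_truth_speed),
            class = "displacement_field")
}

#' Construct a complex frame series
#'
#' Complex acquisition data (OCE M-B-mode frames or ultrasound IQ ensemble)
#' indexed `[depth, lateral, time]` with modality metadata.
#'
#' @param values Complex array `[n_depth, n_lateral, n_time]` with >= 2 frames.
#' @param geometry An `acq_geometry`.
#' @return An object of class `complex_frame_series`.
#' @export
complex_frame_series <- function(values, geometry) {
  stopifnot(inherits(geometry, "acq_geometry"))
  d <- dim(values)
  if (length(d) != 3 || d[3] < 2)
    stop("values must be [depth, lateral, time] with at least 2 frames")
  if (d[1] != length(geometry$depth_positions) ||
      d[2] != length(geometry$lateral_positions))
    stop("array shape inconsistent with geometry axes")
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    stop("frame values must be finite")
  structure(list(values = values, geometry = geometry),
            class = "complex_frame_series")
}

#' Construct a spatiotemporal map
#'
#' Depth-averaged displacement over `[lateral, time]`; the propagating wave
#' appears as a sloped ridge whose inverse slope is the group velocity.
#'
#' @param values Numeric matrix `[n_lateral, n_time]`.
#' @param lateral_positions Strictly monotone lateral coordinates (m).
#' @param frame_rate Frame rate (Hz).
#' @param excitation_position Excitation coordinate on the lateral axis (m).
#' @param direction_tag `"both"`, `"left"` or `"right"` provenance tag.
#' @return An object of class `stmap`.
#' @export
spatio_temporal_map <- function(values, lateral_positions, frame_rate,
                                excitation_position,
                                direction_tag = c("both", "left", "right")) {
  direction_tag <- match.arg(direction_tag)
  if (!is.matrix(values)) stop("values must be a [lateral, time] matrix")
  if (nrow(values) != length(lateral_positions))
    stop("lateral axis length mismatch")
  if (any(diff(lateral_positions) <= 0))
    stop("lateral_positions must be strictly increasing")
  if (!all(is.finite(values))) stop("map values must be finite")
  structure(list(values = values,
                 lateral_positions = as.numeric(lateral_positions),
                 frame_rate = frame_rate,
                 excitation_position = excitation_position,
                 direction_tag = direction_tag),
            class = "stmap")
}

#' Construct a repeated-trial ensemble
#'
#' Repeated wave-speed measurements of one sample (removal/replacement
#' trials), the unit of the Bland-Altman and ICC analyses.
#'
#' @param sample_id Sample label.
#' @param speeds Numeric vector of per-trial speeds (m/s), all > 0, length >= 2.
#' @return An object of class `trial_ensemble`.
#' @export
trial_ensemble <- function(sample_id, speeds) {
  speeds <- as.numeric(speeds)
  if (length(speeds) < 2) stop("a trial ensemble needs at least 2 trials")
  if (any(!is.finite(speeds)) || any(speeds <= 0))
    stop("all trial speeds must be positive and finite")
  structure(list(sample_id = as.character(sample_id), trials = speeds,
                 n_trials = length(speeds)),
            class = "trial_ensemble")
}

#' @export
print.trial_ensemble <- function(x, ...) {
  cat(sprintf("Trial ensemble '%s': %d trials, mean %.4f m/s (SD %.4f)\n",
              x$sample_id, x$n_trials, mean(x$trials), stats::sd(x$trials)))
  invisible(x)
}

#' @export
print.acq_geometry <- function(x, ...) {
  cat(sprintf("%s geometry: %d lateral x %d depth, %.3f mm line, %.0f Hz\n",
              x$modality, length(x$lateral_positions),
              length(x$depth_positions),
              1e3 * diff(range(x$lateral_positions)), x$frame_rate))
  invisible(x)
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Displacement field [%d depth x %d lateral x %d time], %s%s\n",
              d[1], d[2], d[3], x$geometry$modality,
              if (!is.null(x$ground_truth_speed))
                sprintf(", ground truth %.3f m/s", x$ground_truth_speed)
              else ""))
  invisible(x)
}

#' @export
print.stmap <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Spatiotemporal map [%d lateral x %d time], direction '%s'\n",
              d[1], d[2], x$direction_tag))
  invisible(x)
}
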