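---
title: "Methods: transient wave-speed elastography across two tracking modalities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transient wave-speed elastography across two tracking modalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elastowave)
```

## The measurement problem

Transient elastography estimates tissue stiffness by launching a mechanical
impulse and timing the resulting elastic wave as it crosses a tracking line.
Two tracking modalities dominate soft-tissue work:

* **OCE** (phase-sensitive optical coherence elastography): an air-pulse
  excites a surface (Rayleigh) wave, tracked by repeated A-scans at many
  lateral positions (M-B-mode) at a high effective frame rate. The optical
  phase of the complex OCT signal encodes nanometre-scale axial motion.
* **USE** (ultrasound shear wave elastography): an acoustic radiation force
  (ARF) push launches a bulk shear wave tracked in complex-demodulated IQ
  ultrasound data, where slow-time phase shifts encode micrometre motion.

`elastowave` implements both processing chains end to end — displacement
estimation, spatiotemporal mapping, time-of-flight velocimetry, modulus
conversion, and the repeatability statistics used to compare modalities —
plus a synthetic wave-field generator with known ground truth, so every
stage can be validated quantitatively without instrument data.

## Synthetic wave fields

`make_displacement_field()` builds the axial displacement

$$u(z, x, t) = A\, w(z)\, e^{-\alpha |x - x_0|}\, g\!\left(t - \frac{|x - x_0|}{c}\right),$$

a transient pulse launched at the line centre $x_0$ propagating bilaterally
at group velocity $c$. Choices and their reasons:

* **Pulse** $g$: Gaussian-enveloped cosine. Only excitation bandwidths are
  typically reported for such systems (roughly 573 Hz for the air-pulse
  line, 1073 Hz for the ARF push, which we use as the default centre
  frequencies and spectral FWHMs); the Gaussian envelope has an analytic
  spectrum and no sidelobe ringing.
* **Depth profile** $w(z)$: exponential decay from the surface (scale
  300 µm) for the surface wave; for USE a **Gaussian centred on the push
  focus** (scale 2 mm). A kinked profile (e.g. a two-sided exponential)
  is unphysical at an ARF focus and, more importantly, its derivative
  discontinuity leaks into the Loupas local-frequency estimate (below),
  so the smooth profile is the modelling choice here.
* **Amplitudes**: 100 nm (optical tracking scale) and 5 µm (ARF push
  scale) — both comfortably inside each estimator's unambiguous phase
  range.
* **Units**: strict SI internally; kPa and mm only at report boundaries.

Noise is added at the *encoding* stage: circular Gaussian phase noise for
OCE frames (default 0.1 rad in the experiment pipeline) and complex white
noise for IQ (default 10% of signal amplitude). No speckle is simulated;
consequences are discussed under *Limitations*.

Acquisition defaults mirror a realistic instrument pair: a 7.83 mm OCE line
of 251 points at a 30 kHz effective frame rate with a 1310 nm source, and a
USE tracking line at 10 kHz (a typical shear-wave tracking PRF for a linear
array) with a 7.8 MHz centre frequency and a push focused 4 mm deep. The
USE line spans 20 mm: directional f-k filtering needs the transient pulse
to occupy several wavenumber resolution cells, and with a 10 mm aperture a
5 m/s pulse sits only about two cells from $k = 0$, where any quadrant mask
bites into real signal. Twenty millimetres — about half the physical
aperture of a 128-element probe — removes that bias without exceeding what
such a probe can track.

## Displacement estimation

**OCE.** Inter-frame phase differences come from conjugate products of
successive frames, optionally unwrapped along slow time (branch cuts at
$\pi$; a transient pulse rarely wraps more than once, and the flag exists
because some practitioners skip unwrapping). The optical path for a sample
in air is double-pass: $\Delta\phi = (4\pi/\lambda_0)\,[n\,d_z - (n-1)\,d_s]$,
where $d_s$ is the surface motion (the sample surface moving toward the
probe shortens the air path). Inverting gives the corrected displacement

$$d_z = \frac{\lambda_0 \Delta\phi / (4\pi) + (n - 1)\, d_s}{n},$$

with $d_s$ read from the shallowest depth bin whose intensity reaches a
configurable fraction (default 0.5) of the A-scan maximum. Rigid motion
($d_z = d_s$) passes through unchanged for any refractive index — a useful
exactness check. Phase-difference spreads approaching the uniform-noise SD
($\pi/\sqrt{3}$) flag the output as low-SNR rather than returning silent
garbage.

**USE.** The Loupas 2-D autocorrelator over a depth × ensemble kernel
(default 5 × 2): displacement per frame is
$c_s \arg R(0,1) / (4\pi \hat f)$ with the local centre frequency
$\hat f = f_c + \arg R(1,0) / (2\pi T_{fast})$, $T_{fast} = 2\Delta z/c_s$.
With a single-sample depth kernel the correction is undefined and the
estimator reduces exactly to the Kasai lag-one autocorrelator, which the
test suite pins against an independently coded Kasai implementation at
1e-10. Doppler phases approaching $\pm\pi$ (quarter-wavelength per frame)
attach an aliasing warning.

## Mapping and velocimetry

Maps average displacement over a 400 µm depth window — anchored at the
surface (OCE) or centred on the push focus (USE) — then:

1. **Directional filtering** (USE chain): 2-D FFT over (lateral, time);
   quadrants with the sign pairing of the unwanted direction are zeroed
   with a raised-cosine roll-off two bins wide, so the left and right masks
   sum to one off-DC and the two outputs partition the DC-removed input.
   Both axes are zero-padded (factor 2) to suppress circular wrap-around.
   The DC bin belongs to neither direction.
2. **Bilateral split**: each side re-indexed by distance from the source,
   excluding a 0.5 mm near-field zone where time-of-flight is biased.
3. **Arrival times**: normalized cross-correlation of each position's
   trace against the first included position (nearest the source, highest
   SNR before attenuation), with three-point parabolic sub-sample
   refinement; ties in the correlation maximum break toward the smaller
   lag.
4. **Residual-weighted fit**: IRLS with weights
   $w_i = 1/(|r_i| + \varepsilon\,\mathrm{MAD})$, $\varepsilon = 0.01$,
   iterated to a relative slope change below 1e-6 (max 50 iterations); a
   Tukey bisquare variant is available. Exactly collinear input returns
   the ordinary fit with equal weights. Non-positive slopes are flagged
   invalid rather than converted into a speed.

Per-side speed is the inverse slope; the reported group velocity is the
mean of the valid sides. The estimator is equivariant under time dilation
and invariant under amplitude scaling, both asserted as tests.

## Moduli and the Rayleigh correction

Shear-wave speeds convert by $E = 3\rho c^2$; surface-wave speeds by

$$E = \frac{2\rho (1+\nu)^3}{(0.87 + 1.12\nu)^2} C_g^2 .$$

Because OCE measures the Rayleigh wave while USE measures the bulk shear
wave, OCE speeds are divided by the Rayleigh/shear ratio before
comparison. The default ratio solves the Rayleigh secular cubic
$\eta^3 - 8\eta^2 + 8(3 - 2\xi)\eta - 16(1 - \xi) = 0$
(with $\xi = (1-2\nu)/(2(1-\nu))$, root in $(0,1)$, tolerance 1e-12),
giving 95.5% at $\nu = 0.5$; the Viktorov approximation
$(0.87 + 1.12\nu)/(1+\nu)$ (95.3%) is exposed as an alternative. The two
modulus models then agree within 1% at the corrected speed, the residual
reflecting the approximate prefactor of the Rayleigh-modulus formula.

## Repeatability statistics

* **Bland-Altman**: per sample, each trial's difference from the sample
  mean plotted against that mean; bias is the grand mean of differences and
  the limits of agreement are bias ± 1.96 sample SD (n − 1). Normalization
  divides each difference by its sample mean (×100). Differences from a
  sample's own mean sum to zero, so this variant has bias ≡ 0 by
  construction; a leave-one-out variant (difference from the mean of the
  remaining trials) is provided for analyses that need a non-degenerate
  bias, and the two differ exactly by the factor $k/(k-1)$.
* **ICC(2,1)**: two-way random effects, absolute agreement, single
  measurement — the standard choice for "same instrument, repeated
  sessions" repeatability. Computed from the two-way ANOVA mean squares
  and pinned against an explicit sums-of-squares oracle at 1e-10. A
  zero-variance matrix returns 1 with a warning (degenerate perfect
  agreement).
* **MAPE** against a reference modulus, and an OLS **trend fit** of
  difference on mean (two-sided t test) to detect speed-dependent bias.
  Its type-I error calibration (5% ± 1.5% at $\alpha = 0.05$) is asserted
  by simulation in the test suite.

## The experiment pipelines

`run_phantom_experiment()` reproduces the phantom-repeatability design:
eight gelatin samples (two each at 10, 17, 26 and 40 kPa — chosen so the
shear-speed range spans roughly 1.8–3.7 m/s, the plausible range for
gelatin concentrations of 8–14%), five trials each, with 1.5%
removal/replacement speed jitter. Each trial simulates the field (OCE at
the Rayleigh-scaled speed), encodes, decodes, maps, estimates, corrects
and converts, then summarizes Bland-Altman (raw and normalized), ICC,
MAPE and trend fits per modality. `run_anisotropy_experiment()` does the
same at 0°/45°/90° to a fiber axis with speeds from the elliptical profile
$c(\theta) = \sqrt{(c_\parallel\cos\theta)^2 + (c_\perp\sin\theta)^2}$
(defaults 4.4 and 2.4 m/s), reporting per-angle means, per-modality ICC
with angles as subjects, and the between-modality percent difference.

All randomness derives deterministically from the config seed, so a rerun
reproduces the report bit for bit; every summary is recomputable from the
per-trial table, which the tests audit.

Problem sizes in the shipped tests are scaled to what the statistics need:
unit tests run on reduced grids (a few dozen lateral points), while
end-to-end recovery uses the full default geometries at four speeds and
ten noise seeds, and the calibration checks use 10,000 Bland-Altman
differences and 1,000 trend-fit null replicates.

## Limitations

* No speckle: IQ noise is complex white noise, so USE displacement quality
  is optimistic relative to real speckle-tracking data, and the Loupas
  centre-frequency correction is exercised only weakly (ideal baseband
  data has no depth carrier). The Kasai-equivalence and hand-built
  residual-carrier tests cover the correction's algebra instead.
* No dispersion or viscoelasticity: group velocity is the only speed
  quantity; phase-velocity analysis is out of scope.
* The simulator's wave is kinematic (a delayed pulse), not a solution of
  the elastic wave equation: diffraction, mode conversion and near-field
  effects are absent, which is precisely why a near-field exclusion zone
  default of 0.5 mm suffices here; on real data it may need to be larger.
* Passing ground-truth recovery on these synthetic fields demonstrates the
  correctness of the processing chain, not the accuracy of any instrument.
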