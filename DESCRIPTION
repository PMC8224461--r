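Package: elastowave
Title: Side-by-Side Optical Coherence and Ultrasound Shear Wave Elastography Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for transient elastography wave-speed analysis across two
    tracking modalities: phase-sensitive optical coherence elastography (OCE)
    and ultrasound shear wave elastography (USE). Provides a synthetic
    wave-field simulator with known ground-truth speeds, phase-to-displacement
    conversion with surface-motion and refractive-index correction, the Loupas
    two-dimensional autocorrelation displacement estimator, f-k directional
    filtering, depth-averaged spatiotemporal mapping, cross-correlation
    time-of-flight group-velocity estimation with residual-weighted linear
    fitting, Rayleigh-surface-wave and shear-wave Young's modulus conversion
    (including the exact Rayleigh-to-shear speed correction), and
    repeatability statistics (Bland-Altman limits of agreement, two-way
    random-effects intraclass correlation, mean absolute percent error, and
    bias trend fits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
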