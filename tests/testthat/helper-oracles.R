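# Independent oracles, deliberately coded without reusing package internals.

# Kasai lag-one autocorrelator: per-voxel slow-time phase of the lag-one
# conjugate product, no kernel averaging, no frequency correction.
kasai_oracle <- function(iq_values, fc, c_sound) {
  d <- dim(iq_values)
  phi <- Arg(iq_values[, , 2:d[3], drop = FALSE] *
             Conj(iq_values[, , 1:(d[3] - 1), drop = FALSE]))
  du <- c_sound * phi / (4 * pi * fc)
  u <- array(0, dim = d)
  for (t in 2:d[3]) u[, , t] <- u[, , t - 1] + du[, , t - 1]
  u
}

# ICC(2,1) from explicit two-way ANOVA sums of squares.
icc21_oracle <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  gm <- mean(mat)
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  ss_total <- sum((mat - gm)^2)
  ss_rows <- k * sum((row_m - gm)^2)
  ss_cols <- n * sum((col_m - gm)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Brute-force group speed: per lateral position, the raw-field peak arrival
# time on the surface trace; ordinary straight-line fit of time vs distance.
peak_track_speed_oracle <- function(field, exclusion = 0.5e-3) {
  g <- field$geometry
  x <- g$lateral_positions
  x0 <- g$excitation_position
  times <- (seq_len(dim(field$values)[3]) - 1) / g$frame_rate
  keep <- which(x - x0 >= exclusion)
  tt <- vapply(keep, function(i)
    times[which.max(abs(field$values[1, i, ]))], numeric(1))
  dd <- x[keep] - x0
  1 / unname(coef(lm(tt ~ dd))[2])
}

# Brute-force sub-sample lag: cubic-spline resample both traces on a fine
# grid (factor `up`), then integer-lag normalized cross-correlation.
finegrid_lag_oracle <- function(trace, ref, up = 100) {
  nt <- length(ref)
  grid <- seq(1, nt, by = 1 / up)
  tr_f <- spline(seq_len(nt), trace, xout = grid)$y
  ref_f <- spline(seq_len(nt), ref, xout = grid)$y
  n <- length(grid)
  lags <- -(n - 1):(n - 1)
  cc <- convolve(tr_f, ref_f, conj = TRUE, type = "open")
  lags[which.max(cc)] / up
}

# Small geometries to keep unit tests quick; analysis defaults unchanged.
small_oce_geometry <- function(n_lateral = 41, lateral_span = 4e-3,
                               n_depth = 12)
  oce_geometry(n_lateral = n_lateral, lateral_span = lateral_span,
               n_depth = n_depth)

small_use_geometry <- function(n_lateral = 61, lateral_span = 12e-3,
                               n_depth = 15)
  use_geometry(n_lateral = n_lateral, lateral_span = lateral_span,
               n_depth = n_depth)
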