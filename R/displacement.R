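# Column-wise phase unwrap (branch cuts at pi): each column is a series;
# jumps larger than pi between consecutive samples are folded back by 2*pi.
unwrap_phase_cols <- function(m) {
  n <- nrow(m)
  if (n < 2) return(m)
  d <- m[-1, , drop = FALSE] - m[-n, , drop = FALSE]
  adj <- d - 2 * pi * round(d / (2 * pi))
  for (i in 2:n) m[i, ] <- m[i - 1, ] + adj[i - 1, ]
  m
}

# Cumulative sum along the third (time) axis of a [depth, lateral, time] array.
cumsum_time <- function(a) {
  dd <- dim(a)
  if (dd[3] == 1) return(a)
  m <- matrix(a, nrow = dd[1] * dd[2], ncol = dd[3])
  for (j in 2:dd[3]) m[, j] <- m[, j - 1] + m[, j]
  array(m, dim = dd)
}

#' Convert OCE M-B-mode phase to displacement
#'
#' Computes inter-frame phase differences from conjugate products of
#' successive complex frames, optionally unwraps them along slow time, and
#' applies the surface-motion / refractive-index correction for a sample in
#' air: with `ds` the surface displacement increment recovered from the
#' shallowest bright depth bin, the corrected axial increment at depth is
#' `dz = (lambda0 * dphi / (4 pi) + (n - 1) * ds) / n`. Increments are
#' accumulated over slow time into displacement versus time.
#'
#' The surface is located per A-scan as the first depth bin whose mean
#' intensity reaches `surface_threshold` times the A-scan maximum.
#'
#' @param frames A [complex_frame_series()] with OCE geometry.
#' @param surface_threshold Fraction of per-A-scan max intensity used to
#'   locate the surface bin (default 0.5).
#' @param unwrap Unwrap the inter-frame phase-difference series along time
#'   (branch cuts at pi). Default TRUE.
#' @return A [displacement_field()]; time axis matches the input frames with
#'   displacement zero at the first frame. If the phase-difference spread
#'   approaches that of uniform noise the result carries attribute
#'   `low_snr = TRUE` and a warning is issued.
#' @export
oce_phase_to_displacement <- function(frames, surface_threshold = 0.5,
                                      unwrap = TRUE) {
  stopifnot(inherits(frames, "complex_frame_series"))
  g <- frames$geometry
  if (g$modality != "OCE") stop("oce_phase_to_displacement requires OCE frames")
  if (is.null(g$refractive_index_n) || is.null(g$wavelength_lambda0))
    stop("OCE geometry must carry wavelength_lambda0 and refractive_index_n")
  v <- frames$values
  d <- dim(v)
  nz <- d[1]; nx <- d[2]; nt <- d[3]

  dphi <- Arg(v[, , 2:nt, drop = FALSE] * Conj(v[, , 1:(nt - 1), drop = FALSE]))
  if (unwrap && nt > 2) {
    m <- t(matrix(dphi, nrow = nz * nx, ncol = nt - 1))
    dphi <- array(t(unwrap_phase_cols(m)), dim = c(nz, nx, nt - 1))
  }

  # low-SNR guard: uniform phase noise has SD pi/sqrt(3) ~ 1.81 rad
  low_snr <- stats::sd(dphi) > 1.2
  if (low_snr) warning("phase differences look noise-dominated; flagging low SNR")

  intensity <- apply(abs(v), c(1, 2), mean)
  surf_idx <- apply(intensity, 2, function(col) {
    which(col >= surface_threshold * max(col))[1]
  })

  lam <- g$wavelength_lambda0
  n <- g$refractive_index_n
  # surface increment per lateral position and time step
  ds <- (lam / (4 * pi)) *
    do.call(rbind, lapply(seq_len(nx), function(j) dphi[surf_idx[j], j, ]))
  # ds is [lateral, time-1]; broadcast over depth
  ds_full <- aperm(array(ds, dim = c(nx, nt - 1, nz)), c(3, 1, 2))
  dz <- ((lam / (4 * pi)) * dphi + (n - 1) * ds_full) / n

  u <- array(0, dim = c(nz, nx, nt))
  u[, , 2:nt] <- cumsum_time(dz)
  out <- displacement_field(u, g)
  attr(out, "low_snr") <- low_snr
  out
}

#' Loupas 2-D autocorrelation displacement estimator
#'
#' Estimates inter-frame axial displacement from an IQ ensemble by the 2-D
#' autocorrelator: the mean Doppler phase `arg R(0,1)` over a
#' `depth_kernel x ensemble_kernel` kernel is scaled by
#' `c_sound / (4 pi f_hat)`, where `f_hat` is the locally estimated center
#' frequency `f_c + arg R(1,0) / (2 pi T_fast)` with fast-time sampling
#' interval `T_fast = 2 dz / c_sound`. With `depth_kernel = 1` the
#' center-frequency correction is unavailable and the estimator reduces to
#' the Kasai lag-one autocorrelator. Inter-frame estimates are accumulated
#' over slow time.
#'
#' @param frames A [complex_frame_series()] with USE geometry.
#' @param depth_kernel Depth kernel size in samples (>= 1, default 5).
#' @param ensemble_kernel Slow-time kernel size in frames (>= 2, default 2).
#' @return A [displacement_field()] on the input grid (slow-time length
#'   `n_time - ensemble_kernel + 2`; full length for the default kernel).
#'   If any kernel Doppler phase approaches the +/- pi ambiguity limit
#'   (quarter-wavelength displacement per frame) the result carries
#'   attribute `aliasing_warning = TRUE` and a warning is issued.
#' @export
loupas_displacement <- function(frames, depth_kernel = 5, ensemble_kernel = 2) {
  stopifnot(inherits(frames, "complex_frame_series"))
  g <- frames$geometry
  if (g$modality != "USE") stop("loupas_displacement requires USE frames")
  if (is.null(g$us_center_frequency) || is.null(g$sound_speed))
    stop("USE geometry must carry us_center_frequency and sound_speed")
  v <- frames$values
  d <- dim(v)
  nz <- d[1]; nx <- d[2]; nt <- d[3]
  if (depth_kernel < 1 || depth_kernel > nz)
    stop("depth_kernel must be in [1, n_depth]")
  if (ensemble_kernel < 2 || ensemble_kernel > nt)
    stop("ensemble_kernel must be in [2, n_time]")
  M <- ensemble_kernel
  fc <- g$us_center_frequency
  cs <- g$sound_speed
  dz_step <- mean(diff(g$depth_positions))
  t_fast <- 2 * dz_step / cs

  # lag-one slow-time conjugate products [depth, lateral, nt-1]
  p_slow <- v[, , 2:nt, drop = FALSE] * Conj(v[, , 1:(nt - 1), drop = FALSE])
  # lag-one depth conjugate products [nz-1, lateral, nt]
  p_fast <- if (nz > 1)
    v[2:nz, , , drop = FALSE] * Conj(v[1:(nz - 1), , , drop = FALSE])
  else NULL

  # centered moving sum along depth with shrinking windows at the edges
  run_sum_depth <- function(a, k) {
    if (k <= 1) return(a)
    dd <- dim(a)
    half_lo <- floor((k - 1) / 2); half_hi <- k - 1 - half_lo
    m <- matrix(a, nrow = dd[1])
    cs_ <- rbind(0, apply(m, 2, cumsum))
    idx <- seq_len(dd[1])
    lo <- pmax(idx - half_lo, 1); hi <- pmin(idx + half_hi, dd[1])
    out <- cs_[hi + 1, , drop = FALSE] - cs_[lo, , drop = FALSE]
    array(out, dim = dd)
  }

  n_est <- nt - M + 1                      # sliding ensemble windows
  r_slow <- array(0i, dim = c(nz, nx, n_est))
  for (m in seq_len(M - 1)) {
    r_slow <- r_slow + p_slow[, , m:(m + n_est - 1), drop = FALSE]
  }
  r_slow <- run_sum_depth(r_slow, depth_kernel)
  phi_d <- Arg(r_slow)

  if (depth_kernel >= 2 && nz >= 2) {
    n_pairs <- nz - 1
    r_fast <- array(0i, dim = c(n_pairs, nx, n_est))
    for (m in seq_len(M)) {
      r_fast <- r_fast + p_fast[, , m:(m + n_est - 1), drop = FALSE]
    }
    r_fast <- run_sum_depth(r_fast, depth_kernel - 1)
    phi_z <- Arg(r_fast)
    # align the (nz-1)-long pair axis back onto the nz depth grid
    phi_z_full <- array(0, dim = c(nz, nx, n_est))
    phi_z_full[1:n_pairs, , ] <- phi_z
    phi_z_full[nz, , ] <- phi_z[n_pairs, , ]
    f_hat <- fc + phi_z_full / (2 * pi * t_fast)
  } else {
    f_hat <- fc
  }

  aliasing <- max(abs(phi_d)) > 3
  if (aliasing)
    warning("Doppler phase near +/- pi: displacement may exceed the quarter-wavelength ambiguity range")

  du <- cs * phi_d / (4 * pi * f_hat)
  n_out <- n_est + 1
  u <- array(0, dim = c(nz, nx, n_out))
  u[, , 2:n_out] <- cumsum_time(du)
  out <- displacement_field(u, g)
  attr(out, "aliasing_warning") <- aliasing
  out
}
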