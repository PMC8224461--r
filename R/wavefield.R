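#' Depth-average a displacement field into a spatiotemporal map
#'
#' Unweighted mean over the depth bins inside `[z_start, z_start + z_extent]`.
#' By default the window is 400 um anchored at the sample surface (OCE) or
#' centered on the push focal depth (USE), the depth regions used to improve
#' SNR before velocimetry.
#'
#' @param field A [displacement_field()].
#' @param z_start Window start (m); default surface (OCE) or
#'   `push_depth - z_extent / 2` (USE).
#' @param z_extent Window extent (m), default 400 um.
#' @return An [spatio_temporal_map()] tagged `"both"`.
#' @export
depth_average <- function(field, z_start = NULL, z_extent = 400e-6) {
  stopifnot(inherits(field, "displacement_field"))
  g <- field$geometry
  z <- g$depth_positions
  if (is.null(z_start)) {
    z_start <- if (g$modality == "OCE") min(z)
    else {
      zf <- if (is.null(g$push_depth)) mean(range(z)) else g$push_depth
      zf - z_extent / 2
    }
  }
  keep <- which(z >= z_start - 1e-12 & z <= z_start + z_extent + 1e-12)
  if (length(keep) == 0) stop("empty depth window: no bins in [z_start, z_start + z_extent]")
  m <- apply(field$values[keep, , , drop = FALSE], c(2, 3), mean)
  spatio_temporal_map(m, g$lateral_positions, g$frame_rate,
                      g$excitation_position, direction_tag = "both")
}

# Signed FFT frequency indices for an n-point axis (0, 1, ..., -1 ordering).
fft_index <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

#' Directional f-k filter
#'
#' Separates left- and right-moving waves in a spatiotemporal map by zeroing
#' the complementary quadrants of the 2-D (lateral, time) Fourier plane.
#' Quadrant edges use a raised-cosine roll-off a few bins wide so that the
#' left and right masks sum to one everywhere except the DC bin, which is
#' assigned to neither direction; the two outputs therefore partition the
#' DC-removed input.
#'
#' Both axes are zero-padded (doubled, rounded to an FFT-friendly length)
#' before the transform to suppress wrap-around artifacts from the circular
#' FFT; the output is cropped back to the input grid.
#'
#' @param map An [spatio_temporal_map()] with at least 8 lateral and 8 time
#'   samples.
#' @param direction `"left"` (toward decreasing lateral position) or
#'   `"right"`.
#' @param rolloff_bins Half-width of the raised-cosine transition (bins of
#'   the padded grid).
#' @param pad Zero-pad factor per axis (>= 1); default 2.
#' @return A filtered [spatio_temporal_map()] tagged with the direction.
#' @export
directional_filter <- function(map, direction = c("left", "right"),
                               rolloff_bins = 2, pad = 2) {
  direction <- match.arg(direction)
  stopifnot(inherits(map, "stmap"))
  v0 <- map$values
  np0 <- nrow(v0); nt0 <- ncol(v0)
  if (np0 < 8 || nt0 < 8)
    stop("directional filtering needs at least 8 lateral and 8 time samples")
  np <- stats::nextn(ceiling(pad * np0), 2)
  nt <- stats::nextn(ceiling(pad * nt0), 2)
  v <- matrix(0, np, nt)
  v[seq_len(np0), seq_len(nt0)] <- v0

  kx <- fft_index(np)                     # lateral frequency index (rows)
  ft <- fft_index(nt)                     # temporal frequency index (cols)
  # smooth step: 0 for v <= -r, 1 for v >= r, raised cosine between
  step <- function(v, r) {
    s <- 0.5 * (1 + sin(pi * v / (2 * r)))
    s[v <= -r] <- 0; s[v >= r] <- 1
    s
  }
  tk <- step(kx, rolloff_bins)
  tf <- step(ft, rolloff_bins)
  TK <- matrix(tk, np, nt)
  TF <- matrix(tf, np, nt, byrow = TRUE)
  # with R's fft sign convention a wave moving toward +x occupies the
  # quadrants where sign(k) * sign(f) < 0
  w_right <- TK * (1 - TF) + (1 - TK) * TF
  w <- if (direction == "right") w_right else 1 - w_right
  w[1, 1] <- 0                            # DC belongs to neither direction

  F <- stats::fft(v)
  out <- Re(stats::fft(F * w, inverse = TRUE)) / (np * nt)
  out <- out[seq_len(np0), seq_len(nt0), drop = FALSE]
  spatio_temporal_map(out, map$lateral_positions, map$frame_rate,
                      map$excitation_position, direction_tag = direction)
}

#' Split a spatiotemporal map about the excitation position
#'
#' Re-indexes the map into two one-sided maps whose lateral axis is distance
#' from the excitation, each excluding a near-field zone around the source
#' where time-of-flight estimates are biased. The left map's distance axis
#' increases away from the source.
#'
#' @param map An [spatio_temporal_map()] with the excitation strictly inside
#'   the lateral span (a boundary excitation yields a single side with a
#'   warning).
#' @param exclusion Near-field exclusion half-width (m), default 0.5 mm;
#'   must be smaller than the larger half-span.
#' @return A list with elements `left` and `right` (either may be `NULL`
#'   for a boundary excitation), each an `stmap` tagged with its direction
#'   and `excitation_position = 0`.
#' @export
split_bilateral <- function(map, exclusion = 0.5e-3) {
  stopifnot(inherits(map, "stmap"))
  x <- map$lateral_positions
  x0 <- map$excitation_position
  half_span <- max(max(x) - x0, x0 - min(x))
  if (exclusion >= half_span)
    stop("exclusion zone must be smaller than the half-span")

  right_idx <- which(x - x0 >= exclusion)
  left_idx <- rev(which(x0 - x >= exclusion))
  mk_side <- function(idx, dist, tag) {
    if (length(idx) < 3) return(NULL)
    spatio_temporal_map(map$values[idx, , drop = FALSE], dist,
                        map$frame_rate, excitation_position = 0,
                        direction_tag = tag)
  }
  right <- mk_side(right_idx, x[right_idx] - x0, "right")
  left <- mk_side(left_idx, x0 - x[left_idx], "left")
  if (is.null(left) || is.null(right))
    warning("excitation at or near the lateral boundary: single-sided result")
  if (is.null(left) && is.null(right))
    stop("no usable lateral positions outside the exclusion zone")
  list(left = left, right = right)
}
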