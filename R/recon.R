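# Simplified dual-band delay-and-sum reconstruction and MIP rendering, so
# contrast-to-noise can be scored on corrected vs corrupted synthetic scans.
# The clinical system's reconstruction is proprietary; a textbook DAS with
# envelope detection stands in, and all CNR comparisons are therefore
# relative (dB drops), never absolute.

#' Zero-phase band-pass filter along depth
#'
#' Applies the squared magnitude response of a Butterworth band-pass of the
#' given order to every A-line in the frequency domain - exactly the
#' amplitude response of the classic forward-backward (filtfilt)
#' application, with rigorously zero phase. The band-pass is realized as a
#' cascaded Butterworth low-pass at `high` and high-pass at `low`. The two
#' standard display bands are 10-40 MHz (larger structures, rendered red)
#' and 40-120 MHz (smaller structures, rendered green).
#'
#' @param scan A `raw_scan`.
#' @param low,high Band edges in Hz, `0 < low < high < sampling_rate / 2`.
#' @param order Butterworth order per edge (default 4).
#' @return A `raw_scan` with filtered amplitudes.
#' @export
bandpass <- function(scan, low, high, order = 4) {
  stopifnot(inherits(scan, "raw_scan"))
  fs <- scan$config$sampling_rate
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("require 0 < low < high < Nyquist")
  }
  d <- dim(scan$amplitudes)
  n <- d[3L]
  f <- (seq_len(n) - 1) / n * fs
  f <- ifelse(f > fs / 2, fs - f, f) # two-sided magnitude axis
  g_lp <- 1 / (1 + (f / high)^(2 * order))
  ratio <- ifelse(f == 0, 0, (f / low)^(2 * order))
  g_hp <- ratio / (1 + ratio)
  gain <- g_lp * g_hp # |H|^2: zero-phase forward-backward response
  flat <- matrix(aperm(scan$amplitudes, c(3L, 1L, 2L)), nrow = n)
  filt <- Re(stats::mvfft(stats::mvfft(flat) * gain, inverse = TRUE)) / n
  res <- scan
  res$amplitudes <- aperm(array(filt, dim = c(n, d[1L], d[2L])), c(2L, 3L, 1L))
  res
}

#' Delay-and-sum reconstruction
#'
#' For each voxel, A-line amplitudes are summed at the one-way time of
#' flight from the voxel to each scan position within an aperture cone
#' (half-angle `aperture_deg`), with Hann apodization over the lateral
#' offset and normalization by the summed weights; the output volume is the
#' envelope (magnitude of the analytic signal) along depth.
#'
#' @param scan A `raw_scan`.
#' @param grid Optional `list(x =, y =, z =)` voxel centre coordinates in um
#'   (x along fast, y along slow, z depth). Defaults to the scan positions
#'   laterally and every second depth sample axially.
#' @param aperture_deg Aperture half-angle in degrees.
#' @param z_step Depth decimation of the default grid in samples.
#' @param max_radius Cap on the synthetic-aperture lateral radius in um
#'   (bounds the cost; default 150 um, i.e. ten 15 um scan steps).
#' @return 3-D array `[length(x), length(y), length(z)]` with attribute
#'   `grid`.
#' @export
reconstruct_das <- function(scan, grid = NULL, aperture_deg = 25, z_step = 2L,
                            max_radius = 150) {
  stopifnot(inherits(scan, "raw_scan"))
  cfg <- scan$config
  d <- dim(scan$amplitudes)
  dz <- depth_sample_um(cfg)
  x_det <- (seq_len(d[1L]) - 1) * cfg$step_fast
  y_det <- (seq_len(d[2L]) - 1) * cfg$step_slow
  if (is.null(grid)) {
    grid <- list(
      x = x_det, y = y_det,
      z = seq(0, (d[3L] - 1) * dz, by = z_step * dz)
    )
  }
  max_depth <- (d[3L] - 1) * dz
  if (any(grid$z < 0 | grid$z > max_depth) ||
    any(grid$x < min(x_det) - cfg$step_fast | grid$x > max(x_det) + cfg$step_fast) ||
    any(grid$y < min(y_det) - cfg$step_slow | grid$y > max(y_det) + cfg$step_slow)) {
    stop("reconstruction grid must lie inside the scanned volume")
  }
  tan_a <- tan(aperture_deg * pi / 180)
  z <- grid$z
  nz <- length(z)
  r_max <- min(max(z) * tan_a, max_radius)
  n_samples <- d[3L]
  lines <- matrix(aperm(scan$amplitudes, c(3L, 1L, 2L)), nrow = n_samples) # [samples, pos]
  vol <- array(0, dim = c(length(grid$x), length(grid$y), nz))
  fs_per_um <- 1 / dz # samples per um of one-way path

  for (iy in seq_along(grid$y)) {
    dy <- y_det - grid$y[iy]
    for (ix in seq_along(grid$x)) {
      dx <- x_det - grid$x[ix]
      d2 <- outer(dx^2, dy^2, "+") # [n_fast, n_slow]
      sel <- which(d2 <= r_max^2)
      if (length(sel) == 0L) stop("empty aperture for voxel column")
      lat <- sqrt(d2[sel])
      # [nz, ndet] geometry
      dist <- sqrt(outer(z^2, lat^2, "+"))
      samp <- dist * fs_per_um + 1
      inside <- outer(z * tan_a, lat, ">=") # aperture cone gate
      w <- 0.5 * (1 + cos(pi * sweep(
        matrix(lat, nz, length(lat), byrow = TRUE), 1,
        pmax(z * tan_a, 1e-9), "/"
      )))
      w[!inside] <- 0
      i0 <- floor(samp)
      frac <- samp - i0
      ok <- i0 >= 1 & i0 < n_samples
      i0[!ok] <- 1L
      det_col <- matrix(sel, nz, length(sel), byrow = TRUE)
      lin0 <- i0 + (det_col - 1L) * n_samples
      val <- lines[lin0] * (1 - frac) + lines[lin0 + 1L] * frac
      val[!ok] <- 0
      wsum <- rowSums(w)
      wsum[wsum == 0] <- 1
      vol[ix, iy, ] <- rowSums(w * val) / wsum
    }
  }
  # envelope along depth
  flat <- matrix(aperm(vol, c(3L, 1L, 2L)), nrow = nz)
  env <- envelope(flat)
  vol <- aperm(array(env, dim = c(nz, length(grid$x), length(grid$y))), c(2L, 3L, 1L))
  attr(vol, "grid") <- grid
  vol
}

#' Maximum intensity projection
#'
#' Element-wise maximum of a reconstructed volume along one axis. Projecting
#' along depth gives the en-face vasculature view; projecting along the
#' slow axis gives the cross-sectional view used for quality inspection.
#'
#' @param volume 3-D array `[x, y, z]`.
#' @param axis `"depth"`, `"slow"` or `"fast"`.
#' @return A 2-D matrix (depth: `[x, y]`; slow: `[x, z]`; fast: `[y, z]`).
#' @export
mip <- function(volume, axis = c("depth", "slow", "fast")) {
  axis <- match.arg(axis)
  if (length(dim(volume)) != 3L) stop("mip expects a 3-D volume")
  k <- switch(axis, depth = 3L, slow = 2L, fast = 1L)
  apply(volume, setdiff(1:3, k), max)
}

#' Contrast-to-noise ratio of an image
#'
#' CNR is the ratio between the peak intensity inside the feature ROI and
#' the standard deviation of the background ROI, in dB
#' (`20*log10(ip / sb)` on the amplitude-envelope image by default;
#' `db_factor = 10` gives the power convention).
#'
#' @param image 2-D numeric matrix.
#' @param feature_roi,background_roi `list(rows =, cols =)` index ranges;
#'   must be disjoint, background with at least 64 pixels.
#' @param db_factor 20 (default) or 10.
#' @return An object of class `cnr_result` with fields `ip`, `sb`, `cnr_db`.
#' @export
compute_cnr <- function(image, feature_roi, background_roi, db_factor = 20) {
  stopifnot(is.matrix(image))
  roi_cells <- function(roi) {
    as.vector(outer(roi$rows, (roi$cols - 1L) * nrow(image), "+"))
  }
  fcells <- roi_cells(feature_roi)
  bcells <- roi_cells(background_roi)
  if (max(c(fcells, bcells)) > length(image) || min(c(fcells, bcells)) < 1L) {
    stop("ROI outside the image")
  }
  if (length(intersect(fcells, bcells)) > 0L) stop("ROIs must be disjoint")
  if (length(bcells) < 64L) stop("background ROI must contain at least 64 pixels")
  ip <- max(image[fcells])
  sb <- stats::sd(image[bcells])
  if (!is.finite(sb) || sb == 0) stop("background ROI has zero standard deviation")
  if (ip <= 0) stop("feature ROI peak must be positive")
  structure(
    list(ip = ip, sb = sb, cnr_db = db_factor * log10(ip / sb)),
    class = "cnr_result"
  )
}
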