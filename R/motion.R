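# Motion quantification from the raw sinogram: the strongly absorbing
# melanin layer dominates every A-line, so the per-position depth of the
# envelope maximum traces the skin surface. Motion disrupts this surface
# (S_D); smoothing recovers an artificial continuous anatomy (S_C); their
# difference, read out in acquisition order, is the vertical motion graph
# M = S_D - S_C, summarized by M_std, M_max and Q_motion = M_std + beta * M_max.

#' Extract the motion-disrupted skin surface S_D
#'
#' For each scan position the depth of the maximum envelope amplitude inside
#' the depth gate is taken as the melanin-surface depth, refined by 3-point
#' parabolic interpolation so the estimate is not quantized to the depth
#' sample. Positions whose peak fails `min_snr_db` against the scan's noise
#' floor (std over the deepest 20 % of samples) are masked invalid and
#' inpainted from the nearest valid neighbour.
#'
#' @param scan A `raw_scan`.
#' @param depth_gate Integer range `c(first, last)` of depth samples to
#'   search (1-based); default the full recorded range.
#' @param min_snr_db Minimum peak-to-noise-floor ratio in dB for a position
#'   to be trusted.
#' @return A `surface_map` with depths in um.
#' @export
extract_surface <- function(scan, depth_gate = NULL, min_snr_db = 10) {
  stopifnot(inherits(scan, "raw_scan"))
  d <- dim(scan$amplitudes)
  n_samples <- d[3L]
  if (is.null(depth_gate)) depth_gate <- c(1L, n_samples)
  depth_gate <- as.integer(depth_gate)
  if (depth_gate[1L] < 1L || depth_gate[2L] > n_samples || depth_gate[1L] > depth_gate[2L]) {
    stop("depth_gate must be a non-empty range inside the recorded samples")
  }
  dz <- depth_sample_um(scan$config)
  noise_lo <- ceiling(0.8 * n_samples) + 1L
  noise_floor <- stats::sd(as.vector(scan$amplitudes[, , noise_lo:n_samples]))
  if (!is.finite(noise_floor)) noise_floor <- 0

  depth <- matrix(NA_real_, d[1L], d[2L])
  valid <- matrix(FALSE, d[1L], d[2L])
  gate <- depth_gate[1L]:depth_gate[2L]
  for (j in seq_len(d[2L])) {
    # envelope of all fast-axis A-lines of this slow position at once
    block <- t(scan$amplitudes[, j, , drop = TRUE])
    if (d[1L] == 1L) block <- matrix(scan$amplitudes[1L, j, ], ncol = 1L)
    env <- envelope(block) # [n_samples, n_fast]
    for (i in seq_len(d[1L])) {
      e <- env[gate, i]
      k_rel <- which.max(e)
      peak <- e[k_rel]
      ok <- noise_floor == 0 || peak > 0 && 20 * log10(peak / noise_floor) >= min_snr_db
      if (!ok) next
      k_abs <- gate[k_rel]
      # least-squares parabola on the log-envelope around the peak: exact
      # for a Gaussian pulse envelope, and averaging over 7 samples keeps
      # the noise jitter of the depth estimate well below one sample
      delta <- refine_peak_log(env[, i], k_abs)
      depth[i, j] <- (k_abs - 1 + delta) * dz
      valid[i, j] <- TRUE
    }
  }
  if (!any(valid)) stop("no scan position has a detectable surface peak")
  if (!all(valid)) depth <- inpaint_nearest(depth, valid)
  surface_map(depth, valid)
}

# Replace invalid entries by the value of the nearest valid grid neighbour
# (Euclidean distance in scan-position units).
#' @noRd
inpaint_nearest <- function(depth, valid) {
  idx_valid <- which(valid, arr.ind = TRUE)
  idx_bad <- which(!valid, arr.ind = TRUE)
  for (r in seq_len(nrow(idx_bad))) {
    di <- idx_valid[, 1L] - idx_bad[r, 1L]
    dj <- idx_valid[, 2L] - idx_bad[r, 2L]
    nearest <- which.min(di * di + dj * dj)
    depth[idx_bad[r, 1L], idx_bad[r, 2L]] <-
      depth[idx_valid[nearest, 1L], idx_valid[nearest, 2L]]
  }
  depth
}

#' Smooth the disrupted surface into the continuous surface S_C
#'
#' A 2-D median filter removes motion discontinuities and isolated outliers,
#' followed by Gaussian smoothing. Both filters pad the borders by odd
#' (antisymmetric) reflection, so a linear anatomical slope passes through
#' untouched all the way to the map edge. The validity mask is propagated
#' unchanged.
#'
#' The default window of 15 x 9 positions (fast x slow) suppresses motion
#' oscillations faster than about half the window while following the
#' anatomy; when the defaults exceed a small map they are clipped to the
#' map size (an explicitly requested window that does not fit errors).
#'
#' @param s_d A `surface_map` (the disrupted surface).
#' @param median_window Odd window sizes `c(fast, slow)` in positions, or
#'   `NULL` for the default clipped to the map.
#' @param gaussian_sigma Gaussian sigmas `c(fast, slow)` in positions.
#' @return A `surface_map` (the smoothed surface).
#' @export
smooth_surface <- function(s_d, median_window = NULL, gaussian_sigma = c(5, 3)) {
  stopifnot(inherits(s_d, "surface_map"))
  if (is.null(median_window)) {
    odd_clip <- function(w, n) {
      w <- min(w, n)
      if (w %% 2L == 0L) w - 1L else w
    }
    median_window <- c(
      odd_clip(15L, nrow(s_d$depth)),
      odd_clip(9L, ncol(s_d$depth))
    )
  }
  if (any(median_window < 1)) stop("median window must be >= 1 in both axes")
  m <- median_filter2(s_d$depth, median_window)
  m <- gaussian_filter2(m, gaussian_sigma)
  surface_map(m, s_d$valid_mask)
}

#' Form the motion graph M = S_D - S_C
#'
#' The element-wise surface difference is flattened in acquisition order
#' (unidirectional raster: fast index sweeps within each slow index) into a
#' time series with one entry per A-line, `dt = 1 / pulse_rate`.
#'
#' @param s_d,s_c `surface_map`s of identical shape and mask.
#' @param pulse_rate Laser pulse repetition rate in Hz.
#' @return A `motion_graph` in um.
#' @export
motion_graph <- function(s_d, s_c, pulse_rate) {
  stopifnot(inherits(s_d, "surface_map"), inherits(s_c, "surface_map"))
  if (!identical(dim(s_d$depth), dim(s_c$depth))) {
    stop("surface maps must have identical shapes")
  }
  if (!identical(s_d$valid_mask, s_c$valid_mask)) {
    stop("surface maps must carry identical validity masks")
  }
  diff <- s_d$depth - s_c$depth
  # column-major flattening of [n_fast, n_slow] = fast index within slow index
  motion_graph_new(as.vector(diff), dt = 1 / pulse_rate)
}

#' Motion metrics M_std, M_max and the quality index Q_motion
#'
#' `m_std` is the population standard deviation of the displacements about
#' their mean; `m_max` the maximum absolute deviation from the mean (so both
#' are invariant to a constant surface offset); and
#' `q_motion = m_std + beta * m_max`.
#'
#' @param graph A `motion_graph`.
#' @param beta Dimensionless weighting, conventionally `t_std / t_max` of
#'   the calibrated thresholds.
#' @return A `motion_metrics`.
#' @export
#' @examples
#' g <- motion_graph_new(c(3, -4, 0, 1), dt = 0.002)
#' m <- motion_metrics(g, beta = 7 / 75)
#' m$m_max # 4
motion_metrics <- function(graph, beta) {
  stopifnot(inherits(graph, "motion_graph"), is.finite(beta))
  x <- graph$displacement
  mu <- mean(x)
  motion_metrics_new(
    m_std = pop_sd(x),
    m_max = max(abs(x - mu)),
    beta = beta
  )
}

#' Classify a scan's motion against calibrated thresholds
#'
#' Pass iff `q_motion <= tq_motion` (closed boundary by default, so the
#' calibration point itself passes; `strict = TRUE` uses `<`). Per-threshold
#' flags additionally report `m_std > t_std` and `m_max > t_max`, which the
#' overall decision does not use directly.
#'
#' @param metrics A `motion_metrics`.
#' @param thresholds A `threshold_set`.
#' @param strict Use a strict inequality for the pass decision.
#' @return `list(pass = logical, flags = character)`.
#' @export
classify_motion <- function(metrics, thresholds, strict = FALSE) {
  stopifnot(inherits(metrics, "motion_metrics"))
  validate_threshold_set(thresholds)
  pass <- if (strict) {
    metrics$q_motion < thresholds$tq_motion
  } else {
    metrics$q_motion <= thresholds$tq_motion
  }
  flags <- character()
  if (metrics$m_std > thresholds$t_std) flags <- c(flags, "m_std_above_t_std")
  if (metrics$m_max > thresholds$t_max) flags <- c(flags, "m_max_above_t_max")
  list(pass = pass, flags = flags)
}
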