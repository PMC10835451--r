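# Surface-based vertical motion correction: each A-line is shifted along
# depth by the negated motion estimate, with sub-sample interpolation, so
# the melanin surface (and, under the rigid vertical-motion model, every
# absorber beneath it) realigns to the continuous anatomy.

# Shift every A-line so that features move DEEPER by disp[p] um (p in
# acquisition order). Positive shift = injection of downward motion;
# correction uses the negated graph.
#' @noRd
shift_scan <- function(scan, disp_um, method = c("cubic", "linear")) {
  method <- match.arg(method)
  d <- dim(scan$amplitudes)
  n_pos <- d[1L] * d[2L]
  if (length(disp_um) != n_pos) {
    stop(
      "motion graph length (", length(disp_um),
      ") must equal the number of A-lines (", n_pos, ")"
    )
  }
  dz <- depth_sample_um(scan$config)
  shifts <- disp_um / dz
  out <- scan$amplitudes
  ks <- seq_len(d[3L])
  for (j in seq_len(d[2L])) {
    for (i in seq_len(d[1L])) {
      s <- shifts[(j - 1L) * d[1L] + i]
      if (s == 0) next
      # out[k] = in[k - s]: content moves deeper by s samples
      out[i, j, ] <- resample_at(scan$amplitudes[i, j, ], ks - s, method = method)
    }
  }
  res <- scan
  res$amplitudes <- out
  res
}

#' Correct a scan for vertical motion
#'
#' Shifts each A-line along depth by the negative of its motion-graph entry
#' (converted to samples, sub-sample interpolation, zero fill at the window
#' edges), undoing a rigid vertical displacement of the skin. The corrected
#' scan is marked as such in its metadata.
#'
#' @param scan A `raw_scan`.
#' @param motion A `motion_graph` with one entry per A-line.
#' @param method Sub-sample interpolation: `"cubic"` (local Catmull-Rom,
#'   default) or `"linear"`.
#' @return The corrected `raw_scan`.
#' @export
correct_scan <- function(scan, motion, method = c("cubic", "linear")) {
  stopifnot(inherits(scan, "raw_scan"), inherits(motion, "motion_graph"))
  res <- shift_scan(scan, -motion$displacement, method = method)
  res$corrected <- TRUE
  res
}

#' Inject a motion graph into a clean scan
#'
#' The adjoint of [correct_scan()]: shifts each A-line so absorbers appear
#' deeper by the motion entry, emulating vertical skin motion added to
#' motionless raw data. Used to build motion-corrupted datasets for the
#' threshold calibration.
#'
#' @inheritParams correct_scan
#' @return The motion-corrupted `raw_scan`.
#' @export
inject_motion <- function(scan, motion, method = c("cubic", "linear")) {
  stopifnot(inherits(scan, "raw_scan"), inherits(motion, "motion_graph"))
  shift_scan(scan, motion$displacement, method = method)
}

#' Retrieve the motion graph of a scan and correct it
#'
#' The full surface-based chain: extract the disrupted surface, smooth it
#' into the continuous surface, take their difference as the motion graph,
#' and shift the sinogram by its negation.
#'
#' @param scan A `raw_scan` with a detectable melanin surface.
#' @param depth_gate,min_snr_db Passed to [extract_surface()].
#' @param median_window,gaussian_sigma Passed to [smooth_surface()].
#' @param method Interpolation method for the correction shift.
#' @return `list(scan = corrected raw_scan, motion = retrieved motion_graph)`.
#' @export
retrieve_and_correct <- function(scan, depth_gate = NULL, min_snr_db = 10,
                                 median_window = NULL,
                                 gaussian_sigma = c(5, 3),
                                 method = c("cubic", "linear")) {
  s_d <- extract_surface(scan, depth_gate = depth_gate, min_snr_db = min_snr_db)
  s_c <- smooth_surface(s_d, median_window = median_window, gaussian_sigma = gaussian_sigma)
  m <- motion_graph(s_d, s_c, pulse_rate = scan$config$pulse_rate)
  list(scan = correct_scan(scan, m, method = method), motion = m)
}

#' Vertical displacement from a fixed-head point measurement
#'
#' Each repeated A-line is cross-correlated against the first one; the lag
#' of the normalized cross-correlation maximum, refined by parabolic
#' interpolation and converted to um via the depth-sample size, is the
#' vertical displacement at that shot. By construction the first entry is 0,
#' so the graph shows drift relative to the start of the measurement.
#'
#' @param scan A `raw_scan` of kind `"point"` with at least 2 A-lines.
#' @param max_lag Maximum searched lag in samples (default 150, i.e. 225 um
#'   at 1.5 um/sample).
#' @return A `motion_graph` sampled at the pulse rate.
#' @export
point_displacement <- function(scan, max_lag = 150L) {
  stopifnot(inherits(scan, "raw_scan"))
  if (scan$kind != "point") stop("point_displacement expects a point measurement")
  d <- dim(scan$amplitudes)
  n_shots <- d[2L]
  if (n_shots < 2L) stop("need at least 2 A-lines")
  n <- d[3L]
  ref <- scan$amplitudes[1L, 1L, ]
  if (all(ref == 0)) stop("reference A-line is all zeros")
  max_lag <- min(as.integer(max_lag), n - 1L)
  nfft <- 2L * n
  lines <- t(matrix(scan$amplitudes[1L, , ], nrow = n_shots)) # [n_samples, n_shots]
  pad <- rbind(lines, matrix(0, nfft - n, n_shots))
  f_ref <- stats::fft(c(ref, numeric(nfft - n)))
  cc <- Re(stats::mvfft(stats::mvfft(pad) * Conj(f_ref), inverse = TRUE)) / nfft
  # cc[lag + 1, ] = sum_k x_k * ref_{k - lag}; positive lag = content deeper
  lags <- c(0:max_lag, -(max_lag:1))
  rows <- c(1:(max_lag + 1L), (nfft - max_lag + 1L):nfft)
  ccw <- cc[rows, , drop = FALSE]
  norm_ref <- sqrt(sum(ref^2))
  norms <- sqrt(colSums(lines^2))
  dz <- depth_sample_um(scan$config)
  disp <- numeric(n_shots)
  for (s in seq_len(n_shots)) {
    if (norms[s] == 0) {
      disp[s] <- disp[max(1L, s - 1L)]
      next
    }
    v <- ccw[, s] / (norm_ref * norms[s])
    b <- which.max(v)
    lag <- lags[b]
    # parabolic refinement in contiguous lag space
    vm <- v[match(lag - 1L, lags)]
    vp <- v[match(lag + 1L, lags)]
    delta <- if (!is.na(vm) && !is.na(vp)) parabolic_offset(vm, v[b], vp) else 0
    disp[s] <- (lag + delta) * dz
  }
  disp[1L] <- 0
  motion_graph_new(disp, dt = 1 / scan$config$pulse_rate)
}
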