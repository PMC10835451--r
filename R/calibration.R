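# Simulation-based threshold calibration: a ladder of weighted motion graphs
# is injected into a motionless scan, each corrupted dataset is corrected by
# the surface-based algorithm, and the added-vs-retrieved cross-correlation
# C(n) plus the corrected-image CNR trace how performance degrades as motion
# grows. The motion thresholds are read off where CNR has dropped by 1 dB.

#' Default weight ladder of the calibration study
#'
#' Ten weights spanning 0.1 to 3.0 (step ~0.3), so a base graph with std
#' 5 um and max 40 um yields ladder stds 0.5-15 um and maxima 4-120 um.
#'
#' @return Numeric vector of 10 weights.
#' @export
default_weights <- function() {
  seq(0.1, 3, length.out = 10)
}

#' Build the ladder of weighted motion graphs
#'
#' One scaled copy of the base graph per weight (see [scale_motion()]).
#'
#' @param base A non-constant `motion_graph`.
#' @param weights Positive, sorted weights; default [default_weights()].
#' @return List of `motion_graph`s.
#' @export
generate_weighted_motions <- function(base, weights = default_weights()) {
  stopifnot(inherits(base, "motion_graph"))
  if (length(weights) == 0L) stop("weights must be non-empty")
  if (any(weights <= 0) || is.unsorted(weights)) {
    stop("weights must be positive and sorted ascending")
  }
  if (pop_sd(base$displacement) == 0) stop("base graph must be non-constant")
  lapply(weights, function(w) scale_motion(base, w))
}

#' Cross-correlation index between added and retrieved motion graphs
#'
#' The similarity C(n) between the n-th added graph and the n-th retrieved
#' graph: by default the zero-lag, zero-mean, unit-normalized (Pearson)
#' correlation, so identical graphs score 1 and negated graphs -1.
#' `mode = "peak"` instead reports the maximum of the normalized
#' cross-correlation over all lags.
#'
#' @param ma,mr `motion_graph`s of equal length (>= 2).
#' @param mode `"zero_lag"` (default) or `"peak"`.
#' @return A number in `[-1, 1]`.
#' @export
cross_corr_index <- function(ma, mr, mode = c("zero_lag", "peak")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ma, "motion_graph"), inherits(mr, "motion_graph"))
  a <- ma$displacement
  r <- mr$displacement
  if (length(a) != length(r)) stop("graphs must have equal lengths")
  sa <- pop_sd(a)
  sr <- pop_sd(r)
  if (sa == 0 && sr == 0) stop("both graphs are constant; correlation undefined")
  if (sa == 0 || sr == 0) {
    return(0)
  }
  a <- a - mean(a)
  r <- r - mean(r)
  if (mode == "zero_lag") {
    return(sum(a * r) / (length(a) * sa * sr))
  }
  cc <- stats::ccf(a, r, lag.max = length(a) %/% 2L, plot = FALSE, demean = FALSE)
  max(cc$acf) # ccf normalizes by the population sds, matching the zero-lag form
}

#' Run the motion-corruption calibration study
#'
#' For each motion graph in the ladder: inject it into the clean scan
#' (direct A-line shifting of the raw data), run the surface-based
#' retrieve-and-correct chain, score the added-vs-retrieved similarity
#' `c_n`, reconstruct the corrected scan and compute its CNR. The reference
#' CNR comes from the reconstruction of the uncorrupted scan. A constant
#' (zero) added graph scores `c_n = 1` by convention.
#'
#' @param clean_scan A motionless `raw_scan` with a detectable surface.
#' @param motions List of `motion_graph`s (one entry per A-line each).
#' @param rois `list(feature = list(rows =, cols =), background = ...)` in
#'   the coordinates of the cross-sectional (slow-axis) MIP `[x, z]`.
#' @param weights Optional weights recorded alongside the steps.
#' @param grid,aperture_deg,z_step,max_radius Passed to [reconstruct_das()].
#' @param band `c(low, high)` Hz band-pass applied before reconstruction;
#'   defaults to the scan's detection band. `NA` disables filtering.
#' @param cc_mode Passed to [cross_corr_index()].
#' @param ... Passed to [retrieve_and_correct()].
#' @return An object of class `calibration_result` with fields `weights`,
#'   `per_step` (data.frame: weight, m_std, m_max, c_n, cnr_db),
#'   `reference_cnr_db`, `thresholds` (unset, `NULL`).
#' @details The reference CNR is scored on the uncorrupted scan passed
#'   through the same retrieve-and-correct chain as every ladder step, so
#'   the comparison isolates the effect of the added motion rather than of
#'   the processing itself.
#' @export
run_motion_study <- function(clean_scan, motions, rois, weights = NULL,
                             grid = NULL, aperture_deg = 25, z_step = 2L,
                             max_radius = 150, band = NULL,
                             cc_mode = "zero_lag", ...) {
  stopifnot(inherits(clean_scan, "raw_scan"))
  if (is.null(band)) {
    band <- c(clean_scan$config$band_low, clean_scan$config$band_high)
  }
  score_cnr <- function(scan) {
    s <- if (anyNA(band)) scan else bandpass(scan, band[1L], band[2L])
    vol <- reconstruct_das(s,
      grid = grid, aperture_deg = aperture_deg,
      z_step = z_step, max_radius = max_radius
    )
    img <- mip(vol, axis = "slow")
    compute_cnr(img, rois$feature, rois$background)$cnr_db
  }
  reference_cnr_db <- score_cnr(retrieve_and_correct(clean_scan, ...)$scan)
  steps <- lapply(seq_along(motions), function(n) {
    ma <- motions[[n]]
    corrupted <- inject_motion(clean_scan, ma)
    rc <- retrieve_and_correct(corrupted, ...)
    c_n <- if (pop_sd(ma$displacement) == 0) {
      1.0
    } else {
      cross_corr_index(ma, rc$motion, mode = cc_mode)
    }
    mu <- mean(ma$displacement)
    data.frame(
      weight = if (is.null(weights)) NA_real_ else weights[n],
      m_std = pop_sd(ma$displacement),
      m_max = max(abs(ma$displacement - mu)),
      c_n = c_n,
      cnr_db = score_cnr(rc$scan)
    )
  })
  structure(
    list(
      weights = weights,
      per_step = do.call(rbind, steps),
      reference_cnr_db = reference_cnr_db,
      thresholds = NULL
    ),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result %d steps, reference CNR %.2f dB>\n",
    nrow(x$per_step), x$reference_cnr_db
  ))
  print(x$per_step, row.names = FALSE)
  invisible(x)
}

#' End-to-end threshold calibration on a clean scan
#'
#' The canonical simulation study: build the weighted motion ladder from a
#' base graph (default: a physiological graph normalized to std 5 um / max
#' 40 um), inject each rung into the clean scan, retrieve-and-correct with
#' a fixed depth gate around the operator-estimated surface, score
#' added-vs-retrieved cross-correlation and corrected-image CNR, and read
#' the thresholds off the 1 dB CNR drop.
#'
#' Canonical choices (all overridable): the depth gate spans
#' `gate_margin_um` (default 60 um, the phantom's epidermis-to-vessel
#' standoff halved) around the median surface depth of the clean scan; CNR
#' is scored on the high-frequency display band (40 MHz to the detection
#' band edge), the band most sensitive to residual misalignment; the
#' feature ROI is the melanin-surface band (the brightest image feature,
#' whose peak stays anchored); the background ROI pools the quiet zones
#' just above and just below it - coupling medium and papillary gap -
#' where, exactly as in corrupted clinical images, the streaks of
#' incompletely corrected surface land first. The CNR degradation
#' therefore enters through the background standard deviation.
#'
#' The default base graph mirrors how a base motion graph is obtained in
#' practice: raw physiological motion is injected into the clean scan and
#' the *retrieved* graph of that corrupted scan becomes the base (so the
#' base lives in the subspace the surface method can represent, exactly as
#' a graph extracted from a real measurement does), then normalized to
#' std 5 um / max 40 um.
#'
#' @param clean_scan A motionless `raw_scan` of the skin phantom.
#' @param base_motion Optional base `motion_graph` (one entry per A-line);
#'   default derived from `seed` as described above.
#' @param weights Ladder weights.
#' @param seed Integer seed for the default base graph.
#' @param drop_db CNR drop defining the thresholds.
#' @param gate_margin_um Depth-gate half-width around the estimated surface
#'   (default 40 um: enough for the anatomical surface relief, well short
#'   of the vessels - vertical motion beyond it is what the correction
#'   cannot handle).
#' @param feature_band_um Depth band (um, relative to the estimated surface
#'   depth) of the surface feature ROI.
#' @param background_bands_um List of depth bands (um, relative to the
#'   surface) pooled into the background ROI; defaults to the quiet zones
#'   above and below the surface band.
#' @param z_step Depth decimation of the reconstruction grid.
#' @param ... Passed to [run_motion_study()].
#' @return `list(result = calibration_result, thresholds = threshold_set)`;
#'   `result$thresholds` is filled in.
#' @export
calibrate_thresholds <- function(clean_scan, base_motion = NULL,
                                 weights = default_weights(), seed = 1L,
                                 drop_db = 1, gate_margin_um = 40,
                                 feature_band_um = c(-25, 30),
                                 background_bands_um = list(
                                   c(-115, -40),
                                   c(60, 105)
                                 ),
                                 z_step = 3L, ...) {
  cfg <- clean_scan$config
  dz <- depth_sample_um(cfg)
  d0 <- stats::median(extract_surface(clean_scan)$depth)
  gate <- c(
    max(1L, floor((d0 - gate_margin_um) / dz) + 1L),
    min(dim(clean_scan$amplitudes)[3L], ceiling((d0 + gate_margin_um) / dz) + 1L)
  )
  if (is.null(base_motion)) {
    raw <- normalize_motion(make_scan_base_motion(cfg, seed = seed), 5)
    retrieved <- retrieve_and_correct(inject_motion(clean_scan, raw),
      depth_gate = gate
    )$motion
    base_motion <- calibrate_motion(retrieved, target_std = 5, target_max = 40)
  }
  motions <- generate_weighted_motions(base_motion, weights)
  n_samples <- dim(clean_scan$amplitudes)[3L]
  all_bands <- c(background_bands_um, list(feature_band_um))
  z <- seq(
    max(0, d0 + min(unlist(all_bands)) - 10),
    min((n_samples - 1) * dz, d0 + max(unlist(all_bands)) + 10),
    by = z_step * dz
  )
  grid <- list(
    x = (seq_len(cfg$n_fast) - 1) * cfg$step_fast,
    y = (seq_len(cfg$n_slow) - 1) * cfg$step_slow,
    z = z
  )
  zband <- function(band) which(z >= d0 + band[1L] & z <= d0 + band[2L])
  rois <- list(
    feature = list(rows = seq_len(cfg$n_fast), cols = zband(feature_band_um)),
    background = list(
      rows = seq_len(cfg$n_fast),
      cols = sort(unique(unlist(lapply(background_bands_um, zband))))
    )
  )
  band <- c(min(40e6, cfg$band_high / 2), cfg$band_high)
  result <- run_motion_study(clean_scan, motions, rois,
    weights = weights,
    grid = grid, z_step = z_step, band = band, depth_gate = gate, ...
  )
  thresholds <- determine_thresholds(result, drop_db = drop_db)
  result$thresholds <- thresholds
  list(result = result, thresholds = thresholds)
}

#' Determine motion thresholds from the calibration CNR curve
#'
#' `t_std` is the added-motion std at which the corrected-image CNR first
#' falls below `reference_cnr_db - drop_db`, linearly interpolated between
#' the adjacent ladder steps (using the zero-motion reference as the virtual
#' step before the first); `t_max` is the added-motion maximum interpolated
#' at the same point. Then `beta = t_std / t_max` and
#' `tq_motion = t_std + beta * t_max`, which is algebraically `2 * t_std`.
#'
#' @param result A `calibration_result` with `m_std` increasing.
#' @param drop_db CNR drop defining the threshold crossing (default 1 dB).
#' @param r_snr Optional suture SNR reference carried into the set.
#' @return A `threshold_set`.
#' @export
#' @examples
#' res <- structure(list(
#'   per_step = data.frame(
#'     m_std = c(0.5, 2, 3.5, 5, 6.5),
#'     m_max = c(4, 16, 28, 40, 52),
#'     c_n = NA, cnr_db = c(40, 40, 39.5, 38.5, 37)
#'   ),
#'   reference_cnr_db = 40
#' ), class = "calibration_result")
#' determine_thresholds(res)$t_std # 4.25
determine_thresholds <- function(result, drop_db = 1, r_snr = NA_real_) {
  stopifnot(inherits(result, "calibration_result"))
  ps <- result$per_step
  if (nrow(ps) == 0L) stop("calibration result has no steps")
  if (is.unsorted(ps$m_std, strictly = TRUE)) {
    stop("per-step m_std must be strictly increasing")
  }
  target <- result$reference_cnr_db - drop_db
  below <- which(ps$cnr_db < target)
  if (length(below) == 0L) {
    stop("no threshold within ladder: CNR never drops by ", drop_db, " dB")
  }
  k <- below[1L]
  if (k == 1L) {
    prev <- list(m_std = 0, m_max = 0, cnr_db = result$reference_cnr_db)
  } else {
    prev <- ps[k - 1L, ]
  }
  frac <- (prev$cnr_db - target) / (prev$cnr_db - ps$cnr_db[k])
  t_std <- prev$m_std + frac * (ps$m_std[k] - prev$m_std)
  t_max <- prev$m_max + frac * (ps$m_max[k] - prev$m_max)
  threshold_set(t_std, t_max, r_snr = r_snr)
}
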