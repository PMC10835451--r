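#' Acquisition-system configuration
#'
#' Describes the RSOM acquisition geometry and electronics: a focused
#' ultrasound detector raster-scanned over the skin on a fast and a slow
#' mechanical axis, one laser pulse (hence one recorded A-line) per scan
#' position. Time maps to depth via the one-way speed of sound, so one
#' recorded sample spans `speed_of_sound / sampling_rate` metres.
#'
#' Defaults reflect a broadband mesoscopy system: 10--120 MHz detection
#' bandwidth with a 50 MHz centre frequency, 500 Hz pulse repetition rate,
#' and a 15 um scan step.
#'
#' @param n_fast,n_slow Number of scan positions on the fast / slow axis.
#' @param sampling_rate Digitizer rate in samples/s.
#' @param speed_of_sound Acoustic speed in m/s used for the depth mapping.
#' @param step_fast,step_slow Scan step sizes in um.
#' @param pulse_rate Laser pulse repetition rate in Hz (one A-line per pulse).
#' @param center_freq,band_low,band_high Detector centre frequency and band
#'   edges in Hz; `band_low < band_high < sampling_rate / 2`.
#' @param focal_depth Depth of the acoustic focus in um, measured from the
#'   first recorded sample.
#'
#' @return An object of class `system_config`.
#' @export
#' @examples
#' cfg <- system_config(n_fast = 64, n_slow = 16)
#' depth_sample_um(cfg) # 1.5 um per sample
system_config <- function(n_fast, n_slow,
                          sampling_rate = 1e9,
                          speed_of_sound = 1500,
                          step_fast = 15,
                          step_slow = 15,
                          pulse_rate = 500,
                          center_freq = 50e6,
                          band_low = 10e6,
                          band_high = 120e6,
                          focal_depth = 250) {
  cfg <- structure(
    list(
      sampling_rate = as.double(sampling_rate),
      speed_of_sound = as.double(speed_of_sound),
      step_fast = as.double(step_fast),
      step_slow = as.double(step_slow),
      n_fast = as.integer(n_fast),
      n_slow = as.integer(n_slow),
      pulse_rate = as.double(pulse_rate),
      center_freq = as.double(center_freq),
      band_low = as.double(band_low),
      band_high = as.double(band_high),
      focal_depth = as.double(focal_depth)
    ),
    class = "system_config"
  )
  validate_system_config(cfg)
  cfg
}

#' @rdname system_config
#' @param config A `system_config`.
#' @export
depth_sample_um <- function(config) {
  config$speed_of_sound / config$sampling_rate * 1e6
}

#' @noRd
validate_system_config <- function(cfg) {
  if (!inherits(cfg, "system_config")) stop("not a system_config")
  fields <- c(
    "sampling_rate", "speed_of_sound", "step_fast", "step_slow", "n_fast",
    "n_slow", "pulse_rate", "center_freq", "band_low", "band_high",
    "focal_depth"
  )
  for (f in fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("system_config field '", f, "' must be a single strictly positive number")
    }
  }
  if (!(cfg$band_low < cfg$band_high && cfg$band_high < cfg$sampling_rate / 2)) {
    stop("system_config requires band_low < band_high < sampling_rate/2")
  }
  invisible(cfg)
}

#' Raw RSOM scan (sinogram)
#'
#' The 3-D raw-data cube of an RSOM acquisition: one time-resolved pressure
#' A-line per scan position, arranged `[n_fast, n_slow, n_samples]`. The
#' `kind` records what was scanned: a `full` skin scan, a one-line `suture`
#' reference scan (`n_slow == 1`), or a fixed-head `point` measurement
#' (`n_fast == 1`, `n_slow` repeated laser shots).
#'
#' A-lines are timestamped by the unidirectional raster convention: for slow
#' index j, fast index i (both 0-based), the A-line time is
#' `(j * n_fast + i) / pulse_rate` seconds.
#'
#' @param amplitudes Numeric 3-D array `[n_fast, n_slow, n_samples]` of
#'   signed pressure amplitudes (arbitrary units); all values finite.
#' @param config The `system_config` the scan was acquired with.
#' @param kind One of `"full"`, `"suture"`, `"point"`.
#' @param acquisition_order Raster convention; only
#'   `"fast_within_slow"` (unidirectional) is defined.
#'
#' @return An object of class `raw_scan`.
#' @export
raw_scan <- function(amplitudes, config, kind = c("full", "suture", "point"),
                     acquisition_order = "fast_within_slow") {
  kind <- match.arg(kind)
  scan <- structure(
    list(
      amplitudes = amplitudes,
      config = config,
      kind = kind,
      acquisition_order = acquisition_order,
      corrected = FALSE
    ),
    class = "raw_scan"
  )
  validate_raw_scan(scan)
  scan
}

#' @noRd
validate_raw_scan <- function(scan) {
  if (!inherits(scan, "raw_scan")) stop("not a raw_scan")
  validate_system_config(scan$config)
  a <- scan$amplitudes
  if (!is.array(a) || length(dim(a)) != 3L) {
    stop("amplitudes must be a 3-D array [n_fast, n_slow, n_samples]")
  }
  d <- dim(a)
  cfg <- scan$config
  if (d[1L] != cfg$n_fast || d[2L] != cfg$n_slow) {
    stop(
      "amplitudes shape [", d[1L], ", ", d[2L], ", ", d[3L],
      "] inconsistent with config (n_fast = ", cfg$n_fast,
      ", n_slow = ", cfg$n_slow, ")"
    )
  }
  if (scan$kind == "suture" && cfg$n_slow != 1L) {
    stop("a suture scan must have n_slow = 1")
  }
  if (scan$kind == "point" && cfg$n_fast != 1L) {
    stop("a point measurement must have n_fast = 1")
  }
  if (!all(is.finite(a))) {
    stop("dataset 'amplitudes' contains non-finite values")
  }
  if (!identical(scan$acquisition_order, "fast_within_slow")) {
    stop("unknown acquisition_order: ", scan$acquisition_order)
  }
  invisible(scan)
}

#' @export
print.raw_scan <- function(x, ...) {
  d <- dim(x$amplitudes)
  cat(
    sprintf(
      "<raw_scan kind=%s %d x %d positions x %d samples (%.1f um/sample)%s>\n",
      x$kind, d[1L], d[2L], d[3L], depth_sample_um(x$config),
      if (isTRUE(x$corrected)) " corrected" else ""
    )
  )
  invisible(x)
}

#' Skin-surface depth map
#'
#' Per-scan-position depth (um) of the melanin surface, with a validity mask
#' for positions whose surface peak could not be trusted. Holds both the
#' motion-disrupted surface extracted from the raw data and its smoothed,
#' artificially continuous counterpart.
#'
#' @param depth Numeric matrix `[n_fast, n_slow]` of depths in um.
#' @param valid_mask Logical matrix of the same shape; defaults to all-valid.
#' @return An object of class `surface_map`.
#' @export
surface_map <- function(depth, valid_mask = NULL) {
  if (!is.matrix(depth) || !is.numeric(depth)) stop("depth must be a numeric matrix")
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, nrow(depth), ncol(depth))
  if (!is.logical(valid_mask) || !identical(dim(valid_mask), dim(depth))) {
    stop("valid_mask must be a logical matrix matching depth")
  }
  if (!all(is.finite(depth[valid_mask]))) stop("valid depths must be finite")
  structure(list(depth = depth, valid_mask = valid_mask), class = "surface_map")
}

#' Motion graph
#'
#' Vertical skin displacement (um) versus acquisition time, one entry per
#' A-line in acquisition order, sampled every `dt` seconds. Positive values
#' mean the skin moved away from the detector (deeper in the recorded
#' window).
#'
#' @param displacement Finite numeric vector of displacements in um,
#'   length > 1.
#' @param dt Time step between entries in seconds.
#' @return An object of class `motion_graph`.
#' @export
motion_graph_new <- function(displacement, dt) {
  if (!is.numeric(displacement) || length(displacement) < 2L) {
    stop("displacement must be a numeric vector of length > 1")
  }
  if (!all(is.finite(displacement))) stop("displacement must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("dt must be a single positive number")
  }
  structure(
    list(displacement = as.double(displacement), dt = as.double(dt)),
    class = "motion_graph"
  )
}

#' @export
print.motion_graph <- function(x, ...) {
  cat(sprintf(
    "<motion_graph n=%d dt=%.4gs std=%.3g um max|dev|=%.3g um>\n",
    length(x$displacement), x$dt, pop_sd(x$displacement),
    max(abs(x$displacement - mean(x$displacement)))
  ))
  invisible(x)
}

#' Motion metrics (M_std, M_max, Q_motion)
#'
#' Summary statistics of a motion graph: the population standard deviation
#' `m_std`, the maximum absolute deviation from the mean `m_max`, and the
#' quality index `q_motion = m_std + beta * m_max`.
#'
#' @param m_std,m_max Motion statistics in um; `m_max >= m_std >= 0`.
#' @param beta Dimensionless weighting between the two statistics.
#' @return An object of class `motion_metrics`.
#' @export
motion_metrics_new <- function(m_std, m_max, beta) {
  if (m_std < 0) stop("m_std must be >= 0")
  if (m_max < m_std - 1e-9) stop("m_max must be >= m_std")
  structure(
    list(
      m_std = as.double(m_std),
      m_max = as.double(m_max),
      beta = as.double(beta),
      q_motion = as.double(m_std + beta * m_max)
    ),
    class = "motion_metrics"
  )
}

#' Threshold set for the motion quality index
#'
#' Holds the calibrated motion thresholds `t_std` and `t_max` (um), the
#' derived weighting `beta = t_std / t_max`, the quality-index threshold
#' `tq_motion = t_std + beta * t_max` (algebraically `2 * t_std`), and the
#' suture SNR reference `r_snr` (dB) used by the acquisition gate.
#'
#' @param t_std,t_max Motion thresholds in um (strictly positive).
#' @param r_snr Suture SNR reference in dB, or `NA` if no gate is used.
#' @return An object of class `threshold_set`.
#' @export
#' @examples
#' ts <- threshold_set(t_std = 7, t_max = 75, r_snr = 45)
#' ts$tq_motion # 14
threshold_set <- function(t_std, t_max, r_snr = NA_real_) {
  if (!is.finite(t_std) || t_std <= 0) stop("t_std must be a positive number")
  if (!is.finite(t_max) || t_max <= 0) stop("t_max must be a positive number")
  beta <- t_std / t_max
  structure(
    list(
      t_std = as.double(t_std),
      t_max = as.double(t_max),
      beta = beta,
      tq_motion = t_std + beta * t_max,
      r_snr = as.double(r_snr)
    ),
    class = "threshold_set"
  )
}

#' @noRd
validate_threshold_set <- function(ts) {
  if (!inherits(ts, "threshold_set")) stop("not a threshold_set")
  tol <- 1e-9 * (abs(ts$t_std) + 1)
  if (abs(ts$beta - ts$t_std / ts$t_max) > tol) stop("beta != t_std / t_max")
  if (abs(ts$tq_motion - (ts$t_std + ts$beta * ts$t_max)) > tol) {
    stop("tq_motion != t_std + beta * t_max")
  }
  invisible(ts)
}

#' Quality-control report for one scan
#'
#' Machine-readable pass/fail record combining the suture SNR gate and the
#' motion quality index. `motion_pass` is `q_motion <= tq_motion`;
#' `gate_pass` is `suture_snr >= r_snr` (both boundaries closed). If no
#' suture reference accompanies the scan, `suture_snr` and `gate_pass` are
#' `NA` and a flag records the missing reference.
#'
#' @param scan_id Identifier for the scan.
#' @param metrics A `motion_metrics`.
#' @param thresholds A `threshold_set`.
#' @param suture_snr Suture SNR in dB, or `NA`.
#' @param extra_flags Additional character flags to append.
#' @return An object of class `qc_report`.
#' @export
qc_report <- function(scan_id, metrics, thresholds, suture_snr = NA_real_,
                      extra_flags = character()) {
  validate_threshold_set(thresholds)
  cls <- classify_motion(metrics, thresholds)
  flags <- c(cls$flags, extra_flags)
  if (is.na(suture_snr)) {
    gate_pass <- NA
    flags <- c(flags, "no_suture_reference")
  } else {
    gate_pass <- suture_snr >= thresholds$r_snr
  }
  structure(
    list(
      scan_id = as.character(scan_id),
      suture_snr = as.double(suture_snr),
      gate_pass = gate_pass,
      m_std = metrics$m_std,
      m_max = metrics$m_max,
      q_motion = metrics$q_motion,
      thresholds = thresholds,
      motion_pass = cls$pass,
      flags = flags
    ),
    class = "qc_report"
  )
}

#' @noRd
validate_qc_report <- function(rep) {
  if (!inherits(rep, "qc_report")) stop("not a qc_report")
  validate_threshold_set(rep$thresholds)
  if (!identical(rep$motion_pass, rep$q_motion <= rep$thresholds$tq_motion)) {
    stop("motion_pass inconsistent with q_motion and tq_motion")
  }
  if (is.na(rep$suture_snr)) {
    if (!is.na(rep$gate_pass)) stop("gate_pass must be NA when suture_snr is NA")
  } else if (is.na(rep$thresholds$r_snr)) {
    stop("suture_snr present but thresholds carry no r_snr")
  } else if (!identical(rep$gate_pass, rep$suture_snr >= rep$thresholds$r_snr)) {
    stop("gate_pass inconsistent with suture_snr and r_snr")
  }
  invisible(rep)
}

# ---------------------------------------------------------------------------
# File I/O

SCHEMA_VERSION <- 1L

#' Save / load a raw scan container
#'
#' One self-describing container file per scan: the amplitude cube plus all
#' acquisition metadata (`system_config` fields, `kind`,
#' `acquisition_order`, `schema_version`). Serialized with base-R RDS;
#' round trips are bitwise lossless. `load_scan()` re-validates every
#' invariant, so a tampered or inconsistent container is rejected with an
#' error naming the offending dataset.
#'
#' @param scan A validated `raw_scan`.
#' @param path File path (conventionally `.rds`).
#' @return `save_scan()` returns `path` invisibly; `load_scan()` returns the
#'   validated `raw_scan`.
#' @export
save_scan <- function(scan, path) {
  validate_raw_scan(scan)
  payload <- list(
    schema_version = SCHEMA_VERSION,
    amplitudes = scan$amplitudes,
    config = unclass(scan$config),
    kind = scan$kind,
    acquisition_order = scan$acquisition_order,
    corrected = isTRUE(scan$corrected)
  )
  ok <- tryCatch(
    {
      suppressWarnings(saveRDS(payload, path))
      TRUE
    },
    error = function(e) e
  )
  if (!isTRUE(ok)) stop("cannot write scan container to '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' @rdname save_scan
#' @export
load_scan <- function(path) {
  if (!file.exists(path)) stop("scan container not found: ", path)
  payload <- readRDS(path)
  required <- c("schema_version", "amplitudes", "config", "kind", "acquisition_order")
  missing <- setdiff(required, names(payload))
  if (length(missing) > 0L) {
    stop("scan container missing dataset(s): ", paste(missing, collapse = ", "))
  }
  cfg <- do.call(system_config, payload$config[c(
    "n_fast", "n_slow", "sampling_rate", "speed_of_sound", "step_fast",
    "step_slow", "pulse_rate", "center_freq", "band_low", "band_high",
    "focal_depth"
  )])
  scan <- raw_scan(payload$amplitudes, cfg,
    kind = payload$kind,
    acquisition_order = payload$acquisition_order
  )
  scan$corrected <- isTRUE(payload$corrected)
  scan
}

#' Write / read a motion graph as CSV
#'
#' Two-column CSV `time_s,displacement_um` with header, one row per A-line.
#'
#' @param graph A `motion_graph`.
#' @param path CSV file path.
#' @return `write_motion_csv()` returns `path` invisibly; `read_motion_csv()`
#'   returns a `motion_graph`.
#' @export
write_motion_csv <- function(graph, path) {
  stopifnot(inherits(graph, "motion_graph"))
  n <- length(graph$displacement)
  df <- data.frame(
    time_s = (seq_len(n) - 1) * graph$dt,
    displacement_um = graph$displacement
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_csv
#' @export
read_motion_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "displacement_um") %in% names(df))) {
    stop("motion CSV must have columns time_s, displacement_um")
  }
  dt <- if (nrow(df) > 1L) stats::median(diff(df$time_s)) else 1
  motion_graph_new(df$displacement_um, dt)
}

#' Write / read a QC report as JSON
#'
#' The JSON document carries exactly the report fields (thresholds nested),
#' with floats at full precision so round trips are stable. The report's
#' internal consistency (`motion_pass` vs `q_motion`, `gate_pass` vs
#' `suture_snr`) is re-checked before writing and after reading; an
#' inconsistent report is refused.
#'
#' @param report A `qc_report`.
#' @param path JSON file path.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   validated `qc_report`.
#' @export
write_report <- function(report, path) {
  validate_qc_report(report)
  doc <- list(
    scan_id = report$scan_id,
    suture_snr = report$suture_snr,
    gate_pass = report$gate_pass,
    m_std = report$m_std,
    m_max = report$m_max,
    q_motion = report$q_motion,
    thresholds = unclass(report$thresholds),
    motion_pass = report$motion_pass,
    flags = as.list(report$flags)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  ts <- threshold_set(doc$thresholds$t_std, doc$thresholds$t_max,
    r_snr = doc$thresholds$r_snr %||% NA_real_
  )
  beta <- ts$beta
  metrics <- motion_metrics_new(doc$m_std, doc$m_max, beta)
  rep <- qc_report(doc$scan_id, metrics, ts,
    suture_snr = doc$suture_snr %||% NA_real_
  )
  # carry flags verbatim (qc_report recomputes the canonical ones)
  rep$flags <- unlist(doc$flags) %||% character()
  validate_qc_report(rep)
  rep
}
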