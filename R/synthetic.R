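# Forward simulator: skin phantom, suture and point measurements, and
# physiological vertical-motion models. Everything is deterministic given a
# seed, so ground truth is always available for testing the QC chain.

#' Skin phantom specification
#'
#' A stated synthetic world: a strongly absorbing melanin surface layer
#' (plane with optional tilt), sparse dermal vessels (spherical absorbers
#' whose axial extent sets their frequency content), and optionally a 100 um
#' suture line target. Depths are um from the first recorded sample.
#'
#' @param surface_mean_depth Mean depth of the melanin surface in um.
#' @param surface_tilt Length-2 numeric, um of depth change per mm along the
#'   fast and slow axes.
#' @param surface_undulation Smooth anatomical relief of the skin surface
#'   (curvature/texture at the mesoscopic scale): `list(amplitude = um,
#'   period = c(fast_um, slow_um), phase = radians)`; `NULL` for a plane.
#'   Real skin is not a plane, and this relief is what the surface
#'   smoothing has to follow while rejecting motion.
#' @param surface_amplitude Peak pressure amplitude of the surface response
#'   (arbitrary units); the simulated surface SNR is
#'   `20*log10(surface_amplitude / noise_std)`.
#' @param surface_texture Sub-resolution structure of the melanin layer:
#'   each scan position carries one secondary epidermal scatterer at a
#'   static random depth offset below the surface,
#'   `list(offset = c(min_um, max_um), amplitude = c(min, max), seed)`.
#'   In focus the primary surface response dominates; under large vertical
#'   displacement the relative detection sensitivity shifts and the
#'   envelope maximum can wander onto the secondary scatterer - the
#'   layer-thickness ambiguity real surface trackers face. `NULL` disables.
#' @param vessels List of vessels, each `list(center = c(x_um, y_um, z_um),
#'   radius = um, amplitude = units)`.
#' @param suture Optional `list(depth = um, diameter = um, amplitude)`;
#'   diameter defaults to 100 um.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(surface_mean_depth = 250,
                         surface_tilt = c(10, 5),
                         surface_undulation = list(
                           amplitude = 8,
                           period = c(3000, 1500),
                           phase = c(0.7, 2.1)
                         ),
                         surface_amplitude = 1,
                         surface_texture = list(
                           offset = c(12, 16),
                           amplitude = c(0.45, 0.7),
                           seed = 71L
                         ),
                         vessels = list(
                           list(center = c(480, 120, 420), radius = 50, amplitude = 0.6),
                           list(center = c(240, 120, 380), radius = 12, amplitude = 0.5)
                         ),
                         suture = NULL) {
  for (v in vessels) {
    if (v$radius <= 0) stop("vessel radii must be > 0")
    if (v$amplitude <= 0) stop("vessel amplitudes must be > 0")
  }
  if (!is.null(suture)) {
    suture$diameter <- suture$diameter %||% 100
    if (suture$amplitude <= 0) stop("suture amplitude must be > 0")
  }
  structure(
    list(
      surface_mean_depth = surface_mean_depth,
      surface_tilt = rep_len(as.double(surface_tilt), 2L),
      surface_undulation = surface_undulation,
      surface_amplitude = surface_amplitude,
      surface_texture = surface_texture,
      vessels = vessels,
      suture = suture
    ),
    class = "phantom_spec"
  )
}

# Surface depth (um) of a phantom at lateral position (x, y) um.
#' @noRd
phantom_surface_depth <- function(phantom, x, y) {
  d <- phantom$surface_mean_depth +
    phantom$surface_tilt[1L] * x / 1000 +
    phantom$surface_tilt[2L] * y / 1000
  u <- phantom$surface_undulation
  if (!is.null(u)) {
    ph <- rep_len(u$phase %||% 0, 2L)
    d <- d + u$amplitude *
      sin(2 * pi * x / u$period[1L] + ph[1L]) *
      sin(2 * pi * y / u$period[2L] + ph[2L])
  }
  d
}

#' Physiological motion-model specification
#'
#' Vertical skin motion as observed in vivo: ~1 Hz arterial pulsation, slower
#' breathing, sporadic random jumps (muscular movement) and a slow drift.
#' Defaults give a complex mixed pattern on the scale reported for the lower
#' arm (pulsation of order 5-10 um, occasional jumps of tens of um).
#'
#' @param pulse_amp,pulse_freq Pulsation amplitude (um) and frequency (Hz).
#' @param breath_amp,breath_freq Breathing amplitude (um) and frequency (Hz).
#' @param jump_rate Expected random-jump events per second (Poisson).
#' @param jump_amp Maximum magnitude of one signed uniform jump (um).
#' @param drift_std Random-walk drift scale in um per sqrt(s).
#' @param seed Integer seed; identical specs give identical graphs.
#' @return An object of class `motion_model_spec`.
#' @export
motion_model_spec <- function(pulse_amp = 5, pulse_freq = 1,
                              breath_amp = 6, breath_freq = 0.25,
                              jump_rate = 0.15, jump_amp = 25,
                              drift_std = 1, seed = 1L) {
  vals <- c(pulse_amp, pulse_freq, breath_amp, breath_freq, jump_rate, jump_amp, drift_std)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("motion-model amplitudes, frequencies and rates must be finite and >= 0")
  }
  structure(
    list(
      pulse_amp = pulse_amp, pulse_freq = pulse_freq,
      breath_amp = breath_amp, breath_freq = breath_freq,
      jump_rate = jump_rate, jump_amp = jump_amp,
      drift_std = drift_std, seed = as.integer(seed)
    ),
    class = "motion_model_spec"
  )
}

#' Generate a base motion graph
#'
#' Sum of a sinusoidal pulsation, a sinusoidal breathing component,
#' piecewise-constant random jumps (per-sample Poisson-thinned event times
#' with signed uniform amplitudes) and a Gaussian random-walk drift.
#' Deterministic given `spec$seed`.
#'
#' @param spec A `motion_model_spec`.
#' @param duration Total duration in s.
#' @param dt Sample interval in s (`0 < dt < duration`).
#' @return A `motion_graph` of length `round(duration / dt)`.
#' @export
make_base_motion <- function(spec, duration, dt) {
  stopifnot(inherits(spec, "motion_model_spec"))
  if (!is.finite(duration) || !is.finite(dt) || dt <= 0 || duration <= dt) {
    stop("require duration > dt > 0")
  }
  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  pulse <- spec$pulse_amp * sin(2 * pi * spec$pulse_freq * t)
  breath <- spec$breath_amp * sin(2 * pi * spec$breath_freq * t)
  random_part <- with_seed(spec$seed, {
    events <- stats::runif(n) < spec$jump_rate * dt
    sizes <- stats::runif(n, -spec$jump_amp, spec$jump_amp) * events
    jumps <- cumsum(sizes)
    drift <- cumsum(stats::rnorm(n, sd = spec$drift_std * sqrt(dt)))
    jumps + drift
  })
  motion_graph_new(pulse + breath + random_part, dt)
}

#' Rescale a motion graph to a target standard deviation
#'
#' Scalar rescale about the mean so the population standard deviation equals
#' `target_std` exactly; the temporal shape is preserved.
#'
#' @param graph A non-constant `motion_graph`.
#' @param target_std Target population standard deviation in um.
#' @return A `motion_graph`.
#' @export
normalize_motion <- function(graph, target_std) {
  stopifnot(inherits(graph, "motion_graph"))
  s <- pop_sd(graph$displacement)
  if (s == 0) stop("cannot normalize a constant motion graph")
  mu <- mean(graph$displacement)
  motion_graph_new(mu + (graph$displacement - mu) * (target_std / s), graph$dt)
}

#' Scale a motion graph by a weighting value
#'
#' Every displacement entry is multiplied by `weight`, so the standard
#' deviation and maximum absolute value scale by `|weight|` exactly. This is
#' the operation that builds the calibration ladder of weighted motion
#' graphs.
#'
#' @param graph A `motion_graph`.
#' @param weight Finite dimensionless multiplier.
#' @return A `motion_graph`.
#' @export
scale_motion <- function(graph, weight) {
  stopifnot(inherits(graph, "motion_graph"))
  if (!is.finite(weight)) stop("weight must be finite")
  motion_graph_new(graph$displacement * weight, graph$dt)
}

#' Normalize a motion graph to a target std and maximum simultaneously
#'
#' A single scalar rescale cannot set the standard deviation and the maximum
#' absolute deviation independently; calibration base graphs are stated with
#' both (std 5 um, max 40 um). This op centres the graph and alternates an
#' exact max rescale with an odd power transform
#' `y -> max * sign(y) * (|y|/max)^lambda` (monotone, peak-preserving) whose
#' exponent is solved so the population std matches; the fixed point holds
#' both targets to ~1e-9.
#'
#' @param graph A non-constant `motion_graph` (after centring, the ratio
#'   max/std is adjustable on either side of its current value).
#' @param target_std Target population standard deviation, um.
#' @param target_max Target maximum absolute deviation from the mean, um
#'   (`target_max > target_std`).
#' @return A `motion_graph` with mean 0, `pop std = target_std`,
#'   `max|.| = target_max`.
#' @export
calibrate_motion <- function(graph, target_std = 5, target_max = 40) {
  stopifnot(inherits(graph, "motion_graph"))
  if (!(target_max > target_std && target_std > 0)) {
    stop("require target_max > target_std > 0")
  }
  y <- graph$displacement - mean(graph$displacement)
  if (max(abs(y)) == 0) stop("cannot calibrate a constant motion graph")
  transform_std <- function(y, lambda) {
    m <- max(abs(y))
    z <- target_max * sign(y) * (abs(y) / m)^lambda
    z - mean(z)
  }
  for (iter in 1:60) {
    f <- function(lambda) pop_sd(transform_std(y, lambda)) - target_std
    lo <- 0.05
    hi <- 500
    if (f(lo) * f(hi) > 0) stop("target std/max ratio out of reach for this graph shape")
    lambda <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
    y <- transform_std(y, lambda)
    # re-impose the max exactly (centring perturbed it slightly)
    y <- y * (target_max / max(abs(y)))
    if (abs(pop_sd(y) - target_std) < 1e-10 &&
      abs(max(abs(y)) - target_max) < 1e-10) {
      break
    }
  }
  motion_graph_new(y, graph$dt)
}

#' Base motion graph for a scan, emulating clinical sweep pacing
#'
#' In a clinical acquisition one fast sweep takes about 0.53 s (266 steps at
#' 500 Hz), so breathing (~4 s period) spans a handful of slow steps and
#' pulsation (~1 s) nearly alternates between sweeps; that relationship
#' between the physiology and the raster is what makes motion retrieval
#' hard. Desk-scale synthetic scans have shorter sweeps, so the
#' physiological graph is generated over `n_slow * physio_sweep_s` seconds
#' (preserving the clinical per-sweep pacing) and mapped onto the scan's
#' A-line clock, one entry per A-line. Deterministic given `seed`.
#'
#' @param config A `system_config` (fixes the A-line count and rate).
#' @param seed Integer seed for the random motion components.
#' @param spec Optional `motion_model_spec`; defaults to
#'   `motion_model_spec(seed = seed)`.
#' @param physio_sweep_s Emulated duration of one fast sweep in s.
#' @return A `motion_graph` with `n_fast * n_slow` entries.
#' @export
make_scan_base_motion <- function(config, seed = 1L, spec = NULL,
                                  physio_sweep_s = 0.53) {
  stopifnot(inherits(config, "system_config"))
  if (is.null(spec)) spec <- motion_model_spec(seed = seed)
  n_pos <- config$n_fast * config$n_slow
  physio_duration <- config$n_slow * physio_sweep_s
  g <- make_base_motion(spec, duration = physio_duration, dt = physio_duration / n_pos)
  motion_graph_new(g$displacement[seq_len(n_pos)], dt = 1 / config$pulse_rate)
}

# ---------------------------------------------------------------------------
# Forward model

# Gaussian-windowed cosine pulse. sigma_t is set so the -6 dB amplitude full
# bandwidth of the Gaussian envelope spans band_high - band_low.
#' @noRd
pulse_sigma_t <- function(config) {
  bw <- config$band_high - config$band_low
  sqrt(2 * log(2)) / (pi * bw)
}

# Add one absorber's pulse to an A-line (in place semantics via return).
# t0 in seconds; only a +-5 sigma window is touched.
#' @noRd
add_pulse <- function(aline, t0, amp, fs, fc, sigma_t) {
  n <- length(aline)
  k0 <- t0 * fs + 1
  half <- ceiling(5 * sigma_t * fs)
  k_lo <- max(1L, floor(k0 - half))
  k_hi <- min(n, ceiling(k0 + half))
  if (k_lo > k_hi) {
    return(aline)
  }
  tt <- ((k_lo:k_hi) - 1) / fs - t0
  aline[k_lo:k_hi] <- aline[k_lo:k_hi] +
    amp * cos(2 * pi * fc * tt) * exp(-tt^2 / (2 * sigma_t^2))
  aline
}

# Resample a motion graph onto the A-line timestamps of a config
# (unidirectional raster). Returns n_fast * n_slow displacements in um.
#' @noRd
motion_at_alines <- function(motion, config, n_samples) {
  n_pos <- config$n_fast * config$n_slow
  if (is.null(motion)) {
    return(numeric(n_pos))
  }
  stopifnot(inherits(motion, "motion_graph"))
  t_aline <- (seq_len(n_pos) - 1) / config$pulse_rate
  t_graph <- (seq_along(motion$displacement) - 1) * motion$dt
  if (length(motion$displacement) == n_pos) {
    return(motion$displacement)
  }
  if (max(t_graph) < max(t_aline) - 1e-9) {
    stop("motion graph shorter than the scan duration")
  }
  stats::approx(t_graph, motion$displacement, xout = t_aline, rule = 2)$y
}

#' Simulate a raw RSOM scan of a skin phantom
#'
#' Forward model: each A-line is the sum, over all absorbers visible from
#' that scan position, of a Gaussian-windowed cosine pulse (carrier
#' `config$center_freq`, -6 dB bandwidth spanning the detection band)
#' centred at the one-way time of flight of the absorber depth. The melanin
#' surface contributes one absorber per position at its local depth; vessels
#' contribute to positions within two detection beam widths, weighted by a
#' Gaussian lateral sensitivity, with sub-absorbers along their axial extent
#' so that larger vessels carry lower-frequency content. Motion is a rigid
#' vertical offset of every absorber for a given A-line. White Gaussian
#' noise of the given std is added. Deterministic given `seed`.
#'
#' @param phantom A `phantom_spec`.
#' @param config A `system_config`.
#' @param n_samples A-line length in samples.
#' @param motion Optional `motion_graph`, resampled to A-line timestamps;
#'   must cover the scan duration.
#' @param noise_std Additive white Gaussian noise std (signal units).
#' @param seed Integer noise seed.
#' @param beam_sigma Lateral sensitivity (Gaussian sigma) in um.
#' @param focus_sigma Axial width (Gaussian sigma, um) of the focal
#'   sensitivity gain around `config$focal_depth`.
#' @param focus_floor Baseline sensitivity outside the focal zone (the
#'   synthetic-aperture detection of a focused transducer does not fall to
#'   zero off focus).
#' @param kind Scan kind recorded in the output.
#' @return A `raw_scan`.
#' @export
simulate_scan <- function(phantom, config, n_samples = 512L, motion = NULL,
                          noise_std = 0, seed = 1L, beam_sigma = 30,
                          focus_sigma = 50, focus_floor = 0.25,
                          kind = "full") {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(config, "system_config"))
  dz <- depth_sample_um(config)
  max_depth <- (n_samples - 1) * dz
  fs <- config$sampling_rate
  fc <- config$center_freq
  sigma_t <- pulse_sigma_t(config)
  c_um_s <- config$speed_of_sound * 1e6 # um per second, one-way

  disp <- motion_at_alines(motion, config, n_samples)
  amplitudes <- array(0, dim = c(config$n_fast, config$n_slow, n_samples))
  x_pos <- (seq_len(config$n_fast) - 1) * config$step_fast
  y_pos <- (seq_len(config$n_slow) - 1) * config$step_slow

  check_window <- function(depth, what) {
    if (any(depth < 0 | depth > max_depth)) {
      stop(what, " lies outside the recordable depth window [0, ", round(max_depth), "] um")
    }
  }
  check_window(
    range(outer(x_pos, y_pos, function(x, y) phantom_surface_depth(phantom, x, y))),
    "melanin surface"
  )

  # Pre-compute vessel sub-absorbers (axial chord weighting).
  vessel_subs <- lapply(phantom$vessels, function(v) {
    check_window(c(v$center[3] - v$radius, v$center[3] + v$radius), "vessel")
    dz_sub <- dz # one sub-absorber per depth sample across the diameter
    u <- seq(-v$radius, v$radius, by = dz_sub)
    w <- sqrt(pmax(0, 1 - (u / v$radius)^2))
    w <- w / sum(w)
    list(center = v$center, depths = v$center[3] + u, weights = w * v$amplitude)
  })
  cutoff <- 2 * (2.355 * beam_sigma) # ~2 detection beam widths (FWHM)
  sens <- function(z) {
    focus_floor + (1 - focus_floor) *
      exp(-(z - config$focal_depth)^2 / (2 * focus_sigma^2))
  }

  # static per-position melanin-layer texture (secondary epidermal scatterer)
  tex <- phantom$surface_texture
  if (!is.null(tex)) {
    fields <- with_seed(tex$seed %||% 71L, {
      list(
        offset = matrix(
          stats::runif(config$n_fast * config$n_slow, tex$offset[1L], tex$offset[2L]),
          config$n_fast, config$n_slow
        ),
        amp = matrix(
          stats::runif(config$n_fast * config$n_slow, tex$amplitude[1L], tex$amplitude[2L]),
          config$n_fast, config$n_slow
        )
      )
    })
  }

  for (j in seq_len(config$n_slow)) {
    for (i in seq_len(config$n_fast)) {
      p <- (j - 1L) * config$n_fast + i
      aline <- numeric(n_samples)
      d_surface <- phantom_surface_depth(phantom, x_pos[i], y_pos[j]) + disp[p]
      aline <- add_pulse(
        aline, d_surface / c_um_s,
        phantom$surface_amplitude * sens(d_surface),
        fs, fc, sigma_t
      )
      if (!is.null(tex)) {
        d_sec <- d_surface + fields$offset[i, j]
        aline <- add_pulse(
          aline, d_sec / c_um_s,
          phantom$surface_amplitude * fields$amp[i, j] * sens(d_sec),
          fs, fc, sigma_t
        )
      }
      for (vs in vessel_subs) {
        r <- sqrt((x_pos[i] - vs$center[1])^2 + (y_pos[j] - vs$center[2])^2)
        if (r > cutoff) next
        lat <- exp(-r^2 / (2 * beam_sigma^2))
        depths <- vs$depths + disp[p]
        amps <- vs$weights * lat * sens(depths)
        # geometric one-way time of flight (hyperbolic lateral signature)
        dists <- sqrt(depths^2 + r^2)
        for (kk in seq_along(depths)) {
          aline <- add_pulse(
            aline, dists[kk] / c_um_s, amps[kk],
            fs, fc, sigma_t
          )
        }
      }
      if (!is.null(phantom$suture)) {
        # line target along the fast axis (present at every fast position)
        check_window(phantom$suture$depth, "suture")
        d_sut <- phantom$suture$depth + disp[p]
        aline <- add_pulse(
          aline, d_sut / c_um_s,
          phantom$suture$amplitude * sens(d_sut), fs, fc, sigma_t
        )
      }
      amplitudes[i, j, ] <- aline
    }
  }
  if (noise_std > 0) {
    amplitudes <- amplitudes + with_seed(seed, {
      array(stats::rnorm(length(amplitudes), sd = noise_std), dim = dim(amplitudes))
    })
  }
  raw_scan(amplitudes, config, kind = kind)
}

#' Simulate a suture reference scan
#'
#' A one-line scan (`n_slow = 1`) over the 100 um suture attached to the
#' coupling membrane. The suture appears at `suture_depth` across the fast
#' axis; the detector's depth-dependent sensitivity is a Gaussian in depth
#' peaking at `config$focal_depth`, so the recorded amplitude is maximal
#' when the suture sits in the focus.
#'
#' @param config A `system_config` with `n_slow = 1`.
#' @param suture_depth Suture depth in um (inside the recordable window).
#' @param amplitude Peak amplitude the suture would have in focus.
#' @param noise_std Additive white Gaussian noise std.
#' @param seed Integer noise seed.
#' @param n_samples A-line length in samples.
#' @param focus_sigma Depth-sensitivity Gaussian sigma in um.
#' @return A `raw_scan` of kind `"suture"`.
#' @export
make_suture_scan <- function(config, suture_depth, amplitude = 1,
                             noise_std = 0, seed = 1L, n_samples = 512L,
                             focus_sigma = 100) {
  stopifnot(inherits(config, "system_config"), config$n_slow == 1L)
  dz <- depth_sample_um(config)
  if (suture_depth < 0 || suture_depth > (n_samples - 1) * dz) {
    stop("suture depth outside the recordable window")
  }
  sens <- exp(-(suture_depth - config$focal_depth)^2 / (2 * focus_sigma^2))
  fs <- config$sampling_rate
  sigma_t <- pulse_sigma_t(config)
  c_um_s <- config$speed_of_sound * 1e6
  amplitudes <- array(0, dim = c(config$n_fast, 1L, n_samples))
  for (i in seq_len(config$n_fast)) {
    amplitudes[i, 1L, ] <- add_pulse(
      numeric(n_samples), suture_depth / c_um_s,
      amplitude * sens, fs, config$center_freq, sigma_t
    )
  }
  if (noise_std > 0) {
    amplitudes <- amplitudes + with_seed(seed, {
      array(stats::rnorm(length(amplitudes), sd = noise_std), dim = dim(amplitudes))
    })
  }
  raw_scan(amplitudes, config, kind = "suture")
}

#' Simulate a fixed-head point measurement
#'
#' The scanning head stays put while the laser fires at `config$pulse_rate`;
#' each shot records one A-line of the same absorber, displaced vertically
#' by the motion graph. Used to observe physiological skin displacement
#' (e.g. the wrist pulse) over a few seconds.
#'
#' @param config A `system_config` with `n_fast = 1`; `n_slow` is the number
#'   of repeated shots.
#' @param depth Absorber depth in um.
#' @param amplitude Pulse amplitude.
#' @param motion Optional `motion_graph` covering the measurement duration.
#' @param noise_std Additive white Gaussian noise std.
#' @param seed Integer noise seed.
#' @param n_samples A-line length in samples.
#' @return A `raw_scan` of kind `"point"`.
#' @export
make_point_scan <- function(config, depth, amplitude = 1, motion = NULL,
                            noise_std = 0, seed = 1L, n_samples = 256L) {
  stopifnot(inherits(config, "system_config"), config$n_fast == 1L)
  dz <- depth_sample_um(config)
  if (depth < 0 || depth > (n_samples - 1) * dz) {
    stop("absorber depth outside the recordable window")
  }
  disp <- motion_at_alines(motion, config, n_samples)
  fs <- config$sampling_rate
  sigma_t <- pulse_sigma_t(config)
  c_um_s <- config$speed_of_sound * 1e6
  amplitudes <- array(0, dim = c(1L, config$n_slow, n_samples))
  for (j in seq_len(config$n_slow)) {
    amplitudes[1L, j, ] <- add_pulse(
      numeric(n_samples), (depth + disp[j]) / c_um_s,
      amplitude, fs, config$center_freq, sigma_t
    )
  }
  if (noise_std > 0) {
    amplitudes <- amplitudes + with_seed(seed, {
      array(stats::rnorm(length(amplitudes), sd = noise_std), dim = dim(amplitudes))
    })
  }
  raw_scan(amplitudes, config, kind = "point")
}

#' Simulate a cohort of scans with prescribed motion statistics
#'
#' One scan per `(m_std, m_max)` target: a physiological base graph is drawn
#' per scan (seeded reproducibly from `seed`), calibrated to the target
#' statistics via [calibrate_motion()], and injected through the forward
#' model. Ground-truth graphs are returned for recovery testing. A target of
#' `(0, 0)` yields a motionless scan.
#'
#' @param metric_targets List (or n x 2 matrix) of `(m_std, m_max)` pairs in
#'   um; requires `m_max > m_std` (or both zero).
#' @param config A `system_config`.
#' @param phantom A `phantom_spec`.
#' @param noise_std Additive noise std passed to the forward model.
#' @param seed Integer master seed.
#' @param n_samples A-line length.
#' @return List of `list(scan = raw_scan, motion = motion_graph or NULL,
#'   target = c(m_std, m_max))`.
#' @export
make_cohort <- function(metric_targets, config, phantom, noise_std = 0.01,
                        seed = 1L, n_samples = 512L) {
  if (is.matrix(metric_targets)) {
    metric_targets <- lapply(seq_len(nrow(metric_targets)), function(i) metric_targets[i, ])
  }
  lapply(seq_along(metric_targets), function(k) {
    tgt <- metric_targets[[k]]
    if (tgt[1] == 0 && tgt[2] == 0) {
      g <- NULL
    } else {
      if (tgt[2] <= tgt[1]) stop("infeasible target: m_max must exceed m_std")
      base <- make_scan_base_motion(config, seed = derive_seed(seed, k))
      g <- calibrate_motion(base, target_std = tgt[1], target_max = tgt[2])
    }
    scan <- simulate_scan(phantom, config,
      n_samples = n_samples, motion = g,
      noise_std = noise_std, seed = derive_seed(seed, 1000 + k)
    )
    list(scan = scan, motion = g, target = tgt)
  })
}
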