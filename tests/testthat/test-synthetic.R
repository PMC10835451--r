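test_that("make_base_motion composes components and is deterministic", {
  # all amplitudes zero -> all-zero graph
  z <- make_base_motion(
    motion_model_spec(0, 1, 0, 0.25, 0, 0, 0, seed = 1),
    duration = 1, dt = 0.01
  )
  expect_true(all(z$displacement == 0))

  # pure 1 Hz sinusoid over 2 s: exactly 2 periods, max |value| = amplitude
  g <- make_base_motion(
    motion_model_spec(
      pulse_amp = 10, pulse_freq = 1, breath_amp = 0,
      jump_rate = 0, drift_std = 0, seed = 1
    ),
    duration = 2, dt = 0.05
  )
  expect_length(g$displacement, 40L)
  expect_equal(max(abs(g$displacement)), 10)
  # two full periods: zero crossings at 0, 0.5, 1, 1.5 s
  expect_equal(g$displacement[c(1, 11, 21, 31)], rep(0, 4), tolerance = 1e-12)

  spec <- motion_model_spec(seed = 7)
  g1 <- make_base_motion(spec, 3, 0.002)
  g2 <- make_base_motion(spec, 3, 0.002)
  expect_identical(g1$displacement, g2$displacement)

  expect_error(make_base_motion(spec, 0, 0.1), "duration > dt > 0")
  expect_error(motion_model_spec(pulse_amp = -1), ">= 0")
})

test_that("normalize_motion and scale_motion rescale exactly", {
  g <- make_base_motion(motion_model_spec(seed = 2), 3, 0.002)
  n5 <- normalize_motion(g, 5)
  expect_equal(sqrt(mean((n5$displacement - mean(n5$displacement))^2)), 5)
  # re-normalizing back restores the original
  s0 <- sqrt(mean((g$displacement - mean(g$displacement))^2))
  back <- normalize_motion(n5, s0)
  expect_equal(back$displacement, g$displacement, tolerance = 1e-10)
  expect_error(normalize_motion(motion_graph_new(c(2, 2, 2), 1), 5), "constant")

  # scaling: std and max-abs scale linearly, weight 0 zeroes the graph
  base <- normalize_motion(g, 5)
  w3 <- scale_motion(base, 3)
  expect_equal(sqrt(mean((w3$displacement - mean(w3$displacement))^2)), 15)
  expect_equal(max(abs(w3$displacement)), 3 * max(abs(base$displacement)))
  expect_true(all(scale_motion(base, 0)$displacement == 0))
})

test_that("calibrate_motion pins std and max simultaneously", {
  g <- make_base_motion(motion_model_spec(seed = 9), 25, 0.02)
  cal <- calibrate_motion(g, target_std = 5, target_max = 40)
  x <- cal$displacement
  expect_equal(mean(x), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(x^2)), 5, tolerance = 1e-8)
  expect_equal(max(abs(x)), 40, tolerance = 1e-8)
  expect_error(calibrate_motion(g, 5, 4), "target_max > target_std")
})

test_that("forward model places envelope peaks at the time of flight", {
  cfg <- small_config(4L, 2L)
  ph <- flat_phantom(depth = 150)
  scan <- simulate_scan(ph, cfg, n_samples = 256L, noise_std = 0)
  # depth 150 um at 1.5 um/sample -> 0-based sample 100 -> R index 101
  env <- abs(scan$amplitudes[1, 1, ])
  expect_equal(which.max(env), 101L)

  # constant +15 um motion shifts the peak 10 samples deeper
  g <- motion_graph_new(rep(15, 8), dt = 1 / cfg$pulse_rate)
  scan_m <- simulate_scan(ph, cfg, n_samples = 256L, motion = g, noise_std = 0)
  expect_equal(which.max(abs(scan_m$amplitudes[1, 1, ])), 111L)

  # no absorbers, no noise -> all-zero cube
  empty <- phantom_spec(
    surface_mean_depth = 100, surface_tilt = c(0, 0),
    surface_amplitude = 0, vessels = list()
  )
  z <- simulate_scan(empty, cfg, n_samples = 128L, noise_std = 0)
  expect_true(all(z$amplitudes == 0))

  # absorber outside recordable window errors
  expect_error(
    simulate_scan(flat_phantom(depth = 500), cfg, n_samples = 128L),
    "outside the recordable depth window"
  )

  # determinism of the noise
  s1 <- simulate_scan(ph, cfg, n_samples = 128L, noise_std = 0.05, seed = 11)
  s2 <- simulate_scan(ph, cfg, n_samples = 128L, noise_std = 0.05, seed = 11)
  expect_identical(s1$amplitudes, s2$amplitudes)
})

test_that("forward-model fidelity: surface envelope tracks depth + motion", {
  cfg <- small_config(16L, 4L)
  ph <- flat_phantom(depth = 200)
  g <- sinusoid_graph(64, amplitude = 12, period = 17)
  scan <- simulate_scan(ph, cfg, n_samples = 256L, motion = g, noise_std = 0)
  s_d <- extract_surface(scan)
  dz <- depth_sample_um(cfg)
  err <- abs(as.vector(s_d$depth) - (200 + g$displacement))
  expect_lt(max(err), dz)
})

test_that("suture scans carry focus-dependent sensitivity and metadata", {
  cfg <- system_config(n_fast = 266L, n_slow = 1L)
  # duration: 266 points at 500 Hz
  expect_equal(266 / cfg$pulse_rate, 0.532)

  at_focus <- make_suture_scan(cfg, cfg$focal_depth, noise_std = 0)
  off_focus <- make_suture_scan(cfg, cfg$focal_depth + 120, noise_std = 0)
  expect_gt(max(abs(at_focus$amplitudes)), max(abs(off_focus$amplitudes)))
  expect_identical(at_focus$kind, "suture")

  # estimated SNR close to the closed form 20*log10(A / sigma)
  s <- make_suture_scan(cfg, cfg$focal_depth, amplitude = 1, noise_std = 0.01, seed = 2)
  m <- compute_snr(s, expected_depth = cfg$focal_depth)
  expect_lt(abs(m$snr_db - 40), 0.5)

  expect_error(make_suture_scan(cfg, 1e5), "outside the recordable window")
})

test_that("make_cohort hits metric targets and is reproducible", {
  cfg <- small_config(32L, 8L)
  ph <- flat_phantom()
  targets <- list(c(0, 0), c(3, 20), c(7, 75))
  cohort <- make_cohort(targets, cfg, ph, noise_std = 0.01, seed = 5, n_samples = 384L)
  expect_null(cohort[[1]]$motion)
  for (k in 2:3) {
    x <- cohort[[k]]$motion$displacement
    tgt <- targets[[k]]
    expect_equal(sqrt(mean((x - mean(x))^2)), tgt[1], tolerance = 0.05)
    expect_equal(max(abs(x - mean(x))), tgt[2], tolerance = 0.05)
  }
  cohort2 <- make_cohort(targets, cfg, ph, noise_std = 0.01, seed = 5, n_samples = 384L)
  expect_identical(cohort[[3]]$scan$amplitudes, cohort2[[3]]$scan$amplitudes)
  expect_error(make_cohort(list(c(10, 5)), cfg, ph), "infeasible")
})
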