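test_that("extract_surface recovers flat and moving surfaces to one sample", {
  cfg <- small_config(16L, 4L)
  dz <- depth_sample_um(cfg)
  scan <- simulate_scan(flat_phantom(150), cfg, n_samples = 256L, noise_std = 0)
  s_d <- extract_surface(scan)
  expect_true(all(abs(s_d$depth - 150) < dz))
  expect_true(all(s_d$valid_mask))

  g <- sinusoid_graph(64, amplitude = 9, period = 13)
  scan_m <- simulate_scan(flat_phantom(150), cfg,
    n_samples = 256L, motion = g,
    noise_std = 0
  )
  s_m <- extract_surface(scan_m)
  expect_true(all(abs(as.vector(s_m$depth) - (150 + g$displacement)) < dz))

  # a zeroed A-line is masked invalid and inpainted from a neighbour
  scan_z <- simulate_scan(flat_phantom(150), cfg, n_samples = 256L, noise_std = 0.01, seed = 1)
  scan_z$amplitudes[5, 2, ] <- rnorm(256, sd = 0.01)
  s_z <- extract_surface(scan_z, min_snr_db = 20)
  expect_false(s_z$valid_mask[5, 2])
  expect_lt(abs(s_z$depth[5, 2] - 150), 2 * dz)

  expect_error(extract_surface(scan, depth_gate = c(0, 10)), "inside the recorded")
  all_noise <- raw_scan(
    array(rnorm(16 * 4 * 64, sd = 1e-3), dim = c(16, 4, 64)),
    small_config(16L, 4L)
  )
  expect_error(extract_surface(all_noise, min_snr_db = 40), "no scan position")
})

test_that("smooth_surface preserves planes and removes isolated spikes", {
  const <- surface_map(matrix(200, 32, 12))
  expect_equal(smooth_surface(const)$depth, const$depth, tolerance = 1e-9)

  plane <- surface_map(outer(seq_len(32) * 0.8, seq_len(12) * 1.7, "+"))
  sm <- smooth_surface(plane)
  expect_lt(max(abs(sm$depth - plane$depth)), 0.1)

  spiked <- plane
  spiked$depth[16, 6] <- spiked$depth[16, 6] + 50
  sm2 <- smooth_surface(spiked)
  expect_lt(abs(sm2$depth[16, 6] - plane$depth[16, 6]), 1)

  expect_error(smooth_surface(plane, median_window = c(101, 9)), "larger than")
})

test_that("motion_graph flattens S_D - S_C in acquisition order", {
  s_c <- surface_map(matrix(100, 2, 2))
  s_d <- surface_map(matrix(100 + c(1, 2, 3, 4), 2, 2)) # [[1,3],[2,4]] by row
  g <- motion_graph(s_d, s_c, pulse_rate = 500)
  expect_equal(g$displacement, c(1, 2, 3, 4)) # fast index within slow index
  expect_equal(g$dt, 1 / 500)

  expect_equal(
    motion_graph(s_c, s_c, 500)$displacement,
    rep(0, 4)
  )
  s5 <- surface_map(matrix(105, 2, 2))
  expect_equal(motion_graph(s5, s_c, 500)$displacement, rep(5, 4))
  expect_error(motion_graph(surface_map(matrix(1, 3, 2)), s_c, 500), "identical shapes")
})

test_that("motion_metrics matches hand computations and scales homogeneously", {
  g <- motion_graph_new(c(3, -4, 0, 1), dt = 0.002) # mean 0
  m <- motion_metrics(g, beta = 0.5)
  expect_equal(m$m_max, 4)
  expect_equal(m$m_std, sqrt(6.5))
  expect_equal(m$q_motion, sqrt(6.5) + 0.5 * 4)

  z <- motion_metrics(motion_graph_new(rep(0, 8), 0.002), beta = 3)
  expect_equal(c(z$m_std, z$m_max, z$q_motion), c(0, 0, 0))

  # clinically reported pair: m_std 7, m_max 75, beta 7/75 -> q = 14
  mm <- motion_metrics_new(7, 75, beta = 7 / 75)
  expect_equal(mm$q_motion, 14)

  # homogeneity under scaling, exact
  set.seed(8)
  base <- motion_graph_new(rnorm(200), 0.002)
  m1 <- motion_metrics(base, beta = 7 / 75)
  for (k in c(0.5, 2, 13.7)) {
    mk <- motion_metrics(scale_motion(base, k), beta = 7 / 75)
    expect_equal(mk$m_std, k * m1$m_std)
    expect_equal(mk$m_max, k * m1$m_max)
    expect_equal(mk$q_motion, k * m1$q_motion)
  }
})

test_that("m_max >= m_std for 1000 random graphs", {
  set.seed(123)
  for (i in 1:1000) {
    x <- switch(sample(3, 1),
      rnorm(sample(2:50, 1)),
      rcauchy(sample(2:50, 1)),
      runif(sample(2:50, 1), -5, 5)
    )
    m <- motion_metrics(motion_graph_new(x, 0.002), beta = 0.1)
    expect_gte(m$m_max, m$m_std)
  }
})

test_that("classify_motion applies the closed boundary and per-threshold flags", {
  ts <- threshold_set(7, 75)
  zero <- motion_metrics_new(0, 0, beta = ts$beta)
  r <- classify_motion(zero, ts)
  expect_true(r$pass)
  expect_length(r$flags, 0)

  # boundary: q = 14 = tq passes
  boundary <- motion_metrics_new(7, 75, beta = ts$beta)
  expect_true(classify_motion(boundary, ts)$pass)
  expect_false(classify_motion(boundary, ts, strict = TRUE)$pass)

  # m_std flag raised even when the overall decision passes
  m <- motion_metrics_new(10, 12, beta = ts$beta) # q = 10 + 1.12 = 11.12 < 14
  r2 <- classify_motion(m, ts)
  expect_true(r2$pass)
  expect_true("m_std_above_t_std" %in% r2$flags)
  expect_false("m_max_above_t_max" %in% r2$flags)
})

test_that("zero-motion scans stay below the quantization floor", {
  scan <- default_scan_64x16()
  rc <- retrieve_and_correct(scan)
  dz <- depth_sample_um(scan$config)
  m <- motion_metrics(rc$motion, beta = 7 / 75)
  expect_lte(m$q_motion, 2 * dz)
})

test_that("injected motion is recovered end to end", {
  scan <- default_scan_64x16()
  cfg <- scan$config
  base <- make_scan_base_motion(cfg, seed = 21)
  g <- calibrate_motion(base, target_std = 5, target_max = 30)
  corrupted <- inject_motion(scan, g)
  rc <- retrieve_and_correct(corrupted)
  expect_gte(cross_corr_index(g, rc$motion), 0.9)
  inj_std <- sqrt(mean((g$displacement - mean(g$displacement))^2))
  ret_std <- sqrt(mean((rc$motion$displacement - mean(rc$motion$displacement))^2))
  expect_lt(abs(ret_std - inj_std) / inj_std, 0.2)
})
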