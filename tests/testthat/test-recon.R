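tone_scan <- function(freq, n = 512L) {
  cfg <- small_config(2L, 2L)
  tt <- (seq_len(n) - 1) / cfg$sampling_rate
  a <- array(rep(sin(2 * pi * freq * tt), each = 4), dim = c(2, 2, n))
  raw_scan(a, cfg)
}

test_that("bandpass has the prescribed pass/stop behaviour and zero phase", {
  rms <- function(scan) sqrt(mean(scan$amplitudes[1, 1, 100:400]^2))
  # 25 MHz tone through 10-40 MHz: gain >= -1 dB
  s25 <- tone_scan(25e6)
  g25 <- 20 * log10(rms(bandpass(s25, 10e6, 40e6)) / rms(s25))
  expect_gte(g25, -1)
  # 80 MHz tone through 10-40 MHz: gain <= -20 dB
  s80 <- tone_scan(80e6)
  g80 <- 20 * log10(rms(bandpass(s80, 10e6, 40e6)) / rms(s80))
  expect_lte(g80, -20)
  # zero input -> zero output
  z <- tone_scan(25e6)
  z$amplitudes[] <- 0
  expect_true(all(bandpass(z, 10e6, 40e6)$amplitudes == 0))
  # zero phase: in-band tone keeps its zero crossings
  f25 <- bandpass(s25, 10e6, 40e6)
  x <- s25$amplitudes[1, 1, 150:350]
  y <- f25$amplitudes[1, 1, 150:350]
  expect_gt(cor(x, y), 0.999)

  expect_error(bandpass(s25, 0, 40e6), "0 < low")
  expect_error(bandpass(s25, 10e6, 6e8), "Nyquist")
})

test_that("delay-and-sum focuses point absorbers", {
  cfg <- small_config(32L, 8L)
  ph <- point_phantom(232.5, 52.5, 300)
  scan <- simulate_scan(ph, cfg, n_samples = 320L, noise_std = 0)
  vol <- reconstruct_das(scan)
  grid <- attr(vol, "grid")
  idx <- arrayInd(which.max(vol), dim(vol))
  expect_lte(abs(grid$x[idx[1]] - 232.5), cfg$step_fast)
  expect_lte(abs(grid$y[idx[2]] - 52.5), cfg$step_slow)
  expect_lte(abs(grid$z[idx[3]] - 300), 2 * depth_sample_um(cfg) + 1e-9)

  # two absorbers 100 um apart laterally resolve into two maxima
  # (shallow depth and a tight beam so the synthetic aperture resolves them)
  ph2 <- point_phantom(180, 52.5, 150)
  ph2$vessels <- c(ph2$vessels, list(list(center = c(280, 52.5, 150), radius = 6, amplitude = 1)))
  scan2 <- simulate_scan(ph2, cfg, n_samples = 320L, noise_std = 0, beam_sigma = 20)
  vol2 <- reconstruct_das(scan2)
  iz <- which.min(abs(attr(vol2, "grid")$z - 150))
  iy <- which.min(abs(attr(vol2, "grid")$y - 52.5))
  profile <- vol2[, iy, iz]
  i1 <- which.min(abs(attr(vol2, "grid")$x - 180))
  i2 <- which.min(abs(attr(vol2, "grid")$x - 280))
  imid <- which.min(abs(attr(vol2, "grid")$x - 230))
  expect_lt(profile[imid], 0.7 * min(profile[i1], profile[i2]))

  # all-zero scan reconstructs to all zeros
  zscan <- scan
  zscan$amplitudes[] <- 0
  expect_true(all(reconstruct_das(zscan) == 0))

  expect_error(
    reconstruct_das(scan, grid = list(x = 0, y = 0, z = 1e5)),
    "inside the scanned volume"
  )
})

test_that("mip projects the maximum along each axis", {
  vol <- array(0, dim = c(4, 3, 5))
  vol[2, 3, 4] <- 7
  expect_equal(sum(mip(vol, "depth") > 0), 1)
  expect_equal(mip(vol, "depth")[2, 3], 7)
  expect_equal(max(mip(vol, "slow")), max(vol))
  expect_equal(max(mip(vol, "fast")), max(vol))
  expect_error(mip(matrix(0, 2, 2), "depth"), "3-D")
})

test_that("compute_cnr follows its closed form and validates ROIs", {
  img <- matrix(1, 40, 40)
  set.seed(5)
  img[21:40, ] <- rnorm(800, mean = 1, sd = 0.05)
  img[5, 5] <- 10
  fr <- list(rows = 1:10, cols = 1:10)
  bg <- list(rows = 21:40, cols = 1:40)
  r <- compute_cnr(img, fr, bg)
  expect_equal(r$cnr_db, 20 * log10(r$ip / r$sb))
  expect_equal(r$ip, 10)

  # ip = sb -> 0 dB
  img2 <- img
  img2[fr$rows, fr$cols] <- 0
  img2[5, 5] <- sd(img[bg$rows, bg$cols])
  expect_equal(compute_cnr(img2, fr, bg)$cnr_db, 0, tolerance = 1e-9)

  # scale invariance
  r2 <- compute_cnr(img * 123.4, fr, bg)
  expect_equal(r2$cnr_db, r$cnr_db, tolerance = 1e-9)

  expect_error(compute_cnr(img, fr, list(rows = 5:30, cols = 1:40)), "disjoint")
  expect_error(compute_cnr(img, fr, list(rows = 21:22, cols = 1:10)), "64 pixels")
  flat <- matrix(1, 40, 40)
  flat[5, 5] <- 2
  expect_error(compute_cnr(flat, fr, bg), "zero standard deviation")
})

test_that("dual-band images encode the frequency-size relationship", {
  cfg <- small_config(32L, 8L)
  big <- point_phantom(232.5, 52.5, 300)
  big$vessels[[1]]$radius <- 50
  small_v <- point_phantom(232.5, 52.5, 300)
  small_v$vessels[[1]]$radius <- 4
  energy <- function(ph, low, high) {
    s <- simulate_scan(ph, cfg, n_samples = 320L, noise_std = 0)
    sum(bandpass(s, low, high)$amplitudes^2)
  }
  big_low <- energy(big, 10e6, 40e6)
  big_high <- energy(big, 40e6, 120e6)
  small_low <- energy(small_v, 10e6, 40e6)
  small_high <- energy(small_v, 40e6, 120e6)
  expect_gt(big_low / big_high, small_low / small_high)
  expect_gt(big_low, big_high)
  expect_gt(small_high, small_low)
})
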