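test_that("system_config validates fields and derives the depth sampling", {
  cfg <- small_config()
  expect_s3_class(cfg, "system_config")
  expect_equal(depth_sample_um(cfg), 1.5)

  expect_error(system_config(n_fast = 0, n_slow = 4), "strictly positive")
  expect_error(system_config(n_fast = 4, n_slow = 4, band_low = 2e8, band_high = 1e8), "band_low")
  expect_error(
    system_config(n_fast = 4, n_slow = 4, band_low = 1e8, band_high = 6e8),
    "band_low < band_high < sampling_rate/2"
  )
})

test_that("raw_scan enforces shape, kind and finiteness invariants", {
  cfg <- small_config(4L, 2L)
  a <- array(rnorm(4 * 2 * 64), dim = c(4, 2, 64))
  scan <- raw_scan(a, cfg)
  expect_identical(dim(scan$amplitudes), c(4L, 2L, 64L))

  expect_error(raw_scan(array(0, dim = c(3, 2, 64)), cfg), "inconsistent with config")
  expect_error(raw_scan(a, cfg, kind = "suture"), "n_slow = 1")
  expect_error(raw_scan(a, cfg, kind = "point"), "n_fast = 1")
  a[2, 1, 5] <- NaN
  expect_error(raw_scan(a, cfg), "non-finite")
})

test_that("scan containers round-trip losslessly and reject corruption", {
  cfg <- small_config(4L, 2L)
  a <- array(rnorm(4 * 2 * 64), dim = c(4, 2, 64))
  scan <- raw_scan(a, cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_scan(scan, path)
  back <- load_scan(path)
  expect_identical(back$amplitudes, scan$amplitudes)
  expect_identical(unclass(back$config), unclass(scan$config))
  expect_identical(back$kind, "full")

  # suture kind preserved
  sut <- make_suture_scan(small_config(8L, 1L), 250, n_samples = 256L)
  save_scan(sut, path)
  expect_identical(load_scan(path)$kind, "suture")

  # unwritable location
  expect_error(save_scan(scan, file.path(tempdir(), "no_such_dir", "x.rds")), "cannot write")

  # tampered containers: shape mismatch and NaN both refused on load
  payload <- readRDS(path)
  payload$config$n_fast <- 5
  saveRDS(payload, path)
  expect_error(load_scan(path), "inconsistent with config")

  save_scan(scan, path)
  payload <- readRDS(path)
  payload$amplitudes[1, 1, 1] <- NaN
  saveRDS(payload, path)
  expect_error(load_scan(path), "amplitudes")

  payload$amplitudes <- NULL
  saveRDS(payload, path)
  expect_error(load_scan(path), "missing dataset")

  expect_error(load_scan(file.path(tempdir(), "absent.rds")), "not found")
})

test_that("threshold_set derives beta and tq_motion from t_std, t_max", {
  ts <- threshold_set(t_std = 7, t_max = 75, r_snr = 45)
  expect_equal(ts$beta, 7 / 75)
  expect_equal(ts$tq_motion, 14) # t_std + beta * t_max = 2 * t_std
  expect_error(threshold_set(-1, 10), "t_std")
  expect_error(threshold_set(1, 0), "t_max")
})

test_that("qc_report derives pass fields and write_report refuses inconsistency", {
  ts <- threshold_set(7, 75, r_snr = 45)
  g <- motion_graph_new(c(0, 0, 0, 0), 0.002)
  metrics <- motion_metrics(g, beta = ts$beta)
  rep <- qc_report("scan_a", metrics, ts, suture_snr = 44)
  expect_true(rep$motion_pass) # q_motion 0 <= 14
  expect_false(rep$gate_pass) # 44 < 45

  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$q_motion, rep$q_motion)
  expect_identical(back$motion_pass, TRUE)
  expect_identical(back$gate_pass, FALSE)

  # tampered pass flag is refused before write
  bad <- rep
  bad$motion_pass <- FALSE
  expect_error(write_report(bad, path), "motion_pass inconsistent")

  # no suture reference: gate_pass NA plus flag
  rep2 <- qc_report("scan_b", metrics, ts)
  expect_true(is.na(rep2$gate_pass))
  expect_true("no_suture_reference" %in% rep2$flags)
})

test_that("motion graphs round-trip through CSV", {
  g <- motion_graph_new(c(1.25, -0.5, 3, 0), dt = 0.002)
  path <- withr::local_tempfile(fileext = ".csv")
  write_motion_csv(g, path)
  back <- read_motion_csv(path)
  expect_equal(back$displacement, g$displacement)
  expect_equal(back$dt, g$dt)
  expect_error(motion_graph_new(c(1, NA), 0.1), "finite")
  expect_error(motion_graph_new(5, 0.1), "length > 1")
})

test_that("randomized invariant violations are all rejected", {
  cfg <- small_config(4L, 2L)
  base <- array(rnorm(4 * 2 * 32), dim = c(4, 2, 32))
  set.seed(42)
  for (k in 1:20) {
    a <- base
    mode <- sample(c("nan", "inf", "shape"), 1)
    if (mode == "shape") {
      d <- c(4, 2, 32)
      d[sample(1:2, 1)] <- d[sample(1:2, 1)] + sample(c(-1, 1), 1) * sample(1:2, 1)
      d <- pmax(d, 1)
      if (all(d == c(4, 2, 32))) next
      a <- array(0, dim = d)
    } else {
      a[sample(length(a), 1)] <- if (mode == "nan") NaN else Inf
    }
    expect_error(raw_scan(a, cfg))
  }
})
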