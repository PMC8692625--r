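test_that("sensor_frame enforces its invariants", {
  t <- (0:799) / 80
  ch <- matrix(rnorm(800 * 4), 800, 4)
  fr <- sensor_frame(t, ch, nominal_rate = 80)
  expect_equal(nrow(fr$channels), 800)

  t2 <- t; t2[11] <- t2[10] # repeated timestamp
  expect_error(sensor_frame(t2, ch), "index 11")
  expect_error(sensor_frame(t, ch, nominal_rate = 50), "60, 100")
  expect_error(sensor_frame(t * 10, ch, nominal_rate = 80), "inconsistent")
  expect_error(sensor_frame(t, ch[1:10, ]), "one row per timestamp")
})

test_that("CSV write/read round-trips a frame bit for bit", {
  set.seed(1)
  t <- (0:499) / 80
  ch <- matrix(rnorm(500 * 4, 100, 5), 500, 4)
  fr <- sensor_frame(t, ch, units = "lbs", nominal_rate = 80)
  path <- withr::local_tempfile(fileext = ".csv")
  write_frame(fr, path)
  fr2 <- read_frame(path, units = "lbs", nominal_rate = 80)
  expect_identical(fr2$timestamps, fr$timestamps)
  expect_identical(fr2$channels, fr$channels)
})

test_that("read_frame rejects malformed input with located errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,ch0", "0,1", "0.0125,2"), p)
  expect_error(read_frame(p), "missing time column")

  writeLines(c("t,ch0,ch1", "0,1,2", "0.0125,x,3", "0.025,2,4"), p)
  expect_error(read_frame(p), "row 2")

  writeLines(c("t,ch0", "0,1", "0,2", "0.0125,3"), p)
  expect_error(read_frame(p), "index 2")

  expect_error(read_frame(p, format = "hdf5"), "not supported")
})

test_that("two-point calibration maps the anchor points exactly", {
  cal <- two_point_calibrate(1000, 2000, 100)
  expect_equal(au_to_lbs(cal, 1500), 50)
  expect_equal(au_to_lbs(cal, 1000), 0)
  expect_equal(au_to_lbs(cal, 2500), 150) # same line, extrapolated
  expect_error(two_point_calibrate(1000, 1000, 100), "equal")
  expect_error(two_point_calibrate(1000, 2000, -5), "positive")
  # round trip through both anchors is exact
  expect_lt(abs(au_to_lbs(cal, 2000) - 100) / 100, 1e-9)
})

test_that("joint calibration recovers generator gains up to the reference", {
  pl <- simulate_placements(load_lbs = 25,
                            true_gains = c(1.0, 0.9, 1.1, 1.05),
                            n_positions = 5, seed = 4)
  cal <- fit_joint_calibration(pl$frames, known_load = 25)
  rel <- cal$channel_gains / cal$channel_gains[1]
  expect_equal(rel, pl$truth$gains / pl$truth$gains[1], tolerance = 0.01)

  # channels with truly equal sensitivities fit to equal gains
  pl1 <- simulate_placements(true_gains = rep(1, 4), n_positions = 5,
                             seed = 14)
  cal2 <- fit_joint_calibration(pl1$frames)
  expect_equal(cal2$channel_gains, rep(1, 4), tolerance = 0.01)

  expect_error(fit_joint_calibration(pl$frames[1]), "insufficient")
})

test_that("joint calibration equals the normal-equations least-squares oracle", {
  pl <- simulate_placements(seed = 8, n_positions = 6)
  M <- t(vapply(pl$frames, function(f) colMeans(f$channels), numeric(4)))
  # oracle: minimise Var(M %*% c(1, g)) over g by direct normal equations
  Mc <- scale(M, center = TRUE, scale = FALSE)
  g_oracle <- as.numeric(solve(crossprod(Mc[, -1]),
                               -crossprod(Mc[, -1], Mc[, 1])))
  cal <- fit_joint_calibration(pl$frames)
  expect_equal(cal$channel_gains[-1], g_oracle, tolerance = 1e-9)

  # fitted gains do at least as well as the generator's true gains
  v_fit <- var(as.numeric(M %*% cal$channel_gains))
  g_true <- pl$truth$gains / pl$truth$gains[1]
  v_true <- var(as.numeric(M %*% g_true))
  expect_lte(v_fit, v_true + 1e-6)
})

test_that("joint calibration flags degenerate designs", {
  t <- (0:99) / 80
  frames <- lapply(c(5, 9, 13), function(v) {
    ch <- matrix(rep(c(v, 3, v / 2, v / 3), each = 100), 100, 4) +
      matrix(rnorm(400, 0, 1e-6), 100, 4)
    sensor_frame(t, ch)
  })
  expect_error(fit_joint_calibration(frames), "degenerate")
})

test_that("bandpass preserves in-band tones, rejects out-of-band and DC", {
  fs <- 80
  t <- seq(0, 300, by = 1 / fs)
  core <- seq(from = 5 * fs, to = length(t) - 5 * fs)
  inband <- sin(2 * pi * 0.3 * t)
  y <- bandpass(inband, 0.167, 1.5, fs = fs)
  expect_equal(max(abs(y[core])), 1, tolerance = 0.05)

  slow <- sin(2 * pi * 0.05 * t)
  y2 <- bandpass(slow, 0.167, 1.5, fs = fs)
  expect_lt(max(abs(y2[core])), 0.1) # > 90% attenuation

  expect_equal(bandpass(rep(3, 4000), 0.167, 1.5, fs = fs),
               rep(0, 4000), tolerance = 1e-8)
  expect_error(bandpass(inband, 2, 1, fs = fs), "band edges")
  expect_warning(bandpass(inband, 5, 50, fs = fs), "Nyquist")

  # idempotence in the passband
  yy <- bandpass(y, 0.167, 1.5, fs = fs)
  expect_equal(max(abs(yy[core])), max(abs(y[core])), tolerance = 0.05)
})

test_that("moving statistics have exact edge and window semantics", {
  fs <- 80
  expect_equal(moving_stat(rep(2, 800), 1, "variance", fs = fs), rep(0, 800))

  ramp <- seq(0, 1, length.out = 800)
  m <- moving_stat(ramp, 0.5, "mean", fs = fs)
  interior <- 41:760
  expect_equal(m[interior], ramp[interior], tolerance = 1e-10)
  expect_length(m, 800)

  set.seed(7)
  x <- rnorm(80 * 120) # 2 min of unit-variance noise
  v <- moving_stat(x, 10, "variance", fs = fs)
  w <- 10 * fs
  se <- sqrt(2 / (w - 1)) # sampling sd of a window variance
  expect_lt(abs(median(v) - 1), 3 * se)

  expect_error(moving_stat(x[1:10], 10, "mean", fs = fs), "longer than")
  expect_error(moving_stat(x, 0.01, "mean", fs = fs), "2 sample intervals")
})

test_that("steady regions apply the minimum-duration rule exactly", {
  fs <- 80
  t <- (0:(200 * fs - 1)) / fs
  v <- rep(10, length(t))
  v[t >= 20 & t < 28] <- 0.1 # 8 s quiet run
  expect_equal(nrow(steady_regions(bed_series(v, t, fs), threshold = 1,
                                   min_duration_s = 10)), 0)

  v2 <- rep(10, length(t))
  v2[t >= 20 & t < 35] <- 0.1 # 15 s quiet run
  r <- steady_regions(bed_series(v2, t, fs), threshold = 1,
                      min_duration_s = 10)
  expect_equal(nrow(r), 1)
  expect_equal(r$end_s - r$start_s, 15, tolerance = 2 / fs)

  v3 <- rep(0.1, length(t))
  v3[t >= 100 & t < 101] <- 10 # spike splits two quiet runs
  r3 <- steady_regions(bed_series(v3, t, fs), threshold = 1,
                       min_duration_s = 10)
  expect_equal(nrow(r3), 2)
  expect_true(all(diff(c(t(as.matrix(r3[, 1:2])))) > 0)) # ordered, disjoint

  # invariance to high-variance padding
  vp <- c(rep(50, 100), v2, rep(50, 100))
  tp <- (0:(length(vp) - 1)) / fs
  rp <- steady_regions(bed_series(vp, tp, fs), threshold = 1,
                       min_duration_s = 10)
  expect_equal(rp$end_s - rp$start_s, r$end_s - r$start_s,
               tolerance = 2 / fs)
})
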