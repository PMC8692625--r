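test_that("PCA composite recovers a rank-1 source and its loadings", {
  set.seed(21)
  fs <- 80
  t <- (0:(fs * 100 - 1)) / fs
  src <- sin(2 * pi * 0.25 * t) + 0.3 * sin(2 * pi * 0.5 * t)
  w <- c(0.7, 0.5, 0.3, 0.1)
  fr <- sensor_frame(t, outer(src, w), units = "lbs")
  comp <- pca_composite(fr)
  expect_gte(abs(cor(comp$x, src)), 0.999)
  W <- attr(comp, "window_weights")
  wn <- w / sqrt(sum(w^2))
  for (k in seq_len(nrow(W)))
    expect_equal(abs(W[k, ]), wn, tolerance = 1e-6)
})

test_that("an antisymmetric channel pair composites to sqrt(2) the source", {
  fs <- 80
  t <- (0:(fs * 60 - 1)) / fs
  s <- sin(2 * pi * 0.3 * t)
  fr <- sensor_frame(t, cbind(s, -s, 0 * s, 0 * s), units = "lbs")
  comp <- pca_composite(fr)
  expect_gte(abs(cor(comp$x, s)), 0.999)
  expect_equal(sd(comp$x), sqrt(2) * sd(s), tolerance = 0.01)
})

test_that("noise-only channels gain no spurious amplification", {
  set.seed(31)
  fs <- 80
  t <- (0:(fs * 120 - 1)) / fs
  X <- matrix(rnorm(length(t) * 4), ncol = 4)
  fr <- sensor_frame(t, X, units = "lbs")
  comp <- pca_composite(fr)
  expect_lte(var(comp$x), max(apply(X, 2, var)) * 1.2)
})

test_that("breath peaks are found only in steady regions", {
  mv <- data.frame(person = 1, start_s = c(200, 380), duration_s = c(4, 3))
  s <- simulate_session(person_spec(150), movements = mv, noise_sd = 0.02,
                        duration_s = 600, seed = 43)
  comp <- pca_composite(resp_channels(s$frame))
  st <- steady_regions(moving_stat(comp, 5, "variance"), min_duration_s = 10)
  pk <- find_breath_peaks(comp, st)
  in_move <- (pk > 199 & pk < 205) | (pk > 379 & pk < 384)
  expect_equal(sum(in_move), 0)
  expect_gt(length(pk), 100)

  # a 60 s clean region at 15 breaths/min holds 15 +- 1 peaks
  s2 <- simulate_session(person_spec(150, resp_rate = 15), noise_sd = 0.01,
                         duration_s = 90, seed = 2)
  comp2 <- pca_composite(resp_channels(s2$frame))
  pk2 <- find_breath_peaks(comp2,
                           data.frame(start_s = 10, end_s = 70))
  expect_equal(length(pk2), 15, tolerance = 1)

  # a flat region yields no peaks
  flat <- bed_series(rep(0, 80 * 60), (0:(80 * 60 - 1)) / 80, 80)
  expect_length(find_breath_peaks(flat), 0)
})

test_that("rate epochs use the median inter-peak interval", {
  pk <- seq(0, 600, by = 3)
  rr <- respiratory_rate(pk, 600)
  expect_true(all(rr$rate_bpm[rr$valid] == 20))

  # one apnea-length gap does not move the median
  pk2 <- c(seq(0, 150, by = 3), seq(160, 300, by = 3))
  rr2 <- respiratory_rate(pk2, 300)
  expect_true(all(rr2$rate_bpm[rr2$valid] == 20))

  # too few peaks and unsteady windows are flagged, not guessed
  rr3 <- respiratory_rate(c(1, 2), 300, steady = data.frame(start_s = 0,
                                                            end_s = 100))
  expect_true(any(!rr3$valid & rr3$reason_invalid == "unsteady"))
  rr4 <- respiratory_rate(numeric(0), 60)
  expect_true(all(!rr4$valid & rr4$reason_invalid == "too_few_peaks"))
})

test_that("a stationary night is recovered within half a breath per minute", {
  s <- simulate_session(person_spec(150, resp_rate = 17), noise_sd = 0.05,
                        duration_s = 480, seed = 17)
  comp <- pca_composite(resp_channels(s$frame))
  pk <- find_breath_peaks(comp)
  rr <- respiratory_rate(pk, 480)
  expect_true(all(abs(rr$rate_bpm[rr$valid] - 17) <= 0.5))
})

test_that("composite tracks the source at least as well as any channel", {
  s <- two_sleeper_session(seed = 3, duration_s = 300, rr1 = 14, rr2 = 19)
  rc <- resp_channels(s$frame)
  comp <- pca_composite(rc)
  src <- bandpass(s$truth$sources[, 1] + s$truth$sources[, 2],
                  0.167, 1.5, fs = 80)
  best_chan <- max(abs(cor(rc$channels, src)))
  expect_gte(abs(cor(comp$x, src)), best_chan - 0.01)
})

test_that("apneas are detected with their durations and kinds", {
  aps <- list(apnea_spec(100, 11, "central"),
              apnea_spec(180, 22, "central"),
              apnea_spec(300, 45, "obstructive", effort_fraction = 0.2),
              apnea_spec(460, 81, "central"),
              apnea_spec(600, 8, "central"))
  s <- simulate_session(person_spec(150, resp_rate = 15), apneas = aps,
                        noise_sd = 0.01, duration_s = 720, seed = 6)
  ap <- detect_apneas(pca_composite(resp_channels(s$frame)))
  tr <- s$truth$apneas
  tr_rep <- tr[tr$duration_s > 10, ]
  expect_equal(nrow(ap), nrow(tr_rep)) # the 8 s gap is not an apnea
  o <- order(ap$start_s)
  expect_equal(ap$duration_s[o], tr_rep$duration_s, tolerance = 0.5 / 22)
  expect_true(all(abs(ap$duration_s[o] - tr_rep$duration_s) <= 0.5))
  expect_equal(ap$kind[o], tr_rep$kind)
  obs <- ap$kind == "obstructive"
  expect_true(all(ap$effort_amplitude_fraction[obs] >= 0.05 &
                    ap$effort_amplitude_fraction[obs] < 0.5))
})

test_that("periodic breathing is flagged only above the 30 s cycle floor", {
  s <- simulate_session(person_spec(150, resp_rate = 15), noise_sd = 0.01,
                        duration_s = 900, seed = 41)
  comp <- pca_composite(resp_channels(s$frame))
  modulate <- function(period) {
    m <- pmax(1 + 0.8 * sin(2 * pi * comp$t / period) - 0.8, 0.05)
    resp_envelope(bed_series(comp$x * m, comp$t, comp$fs))
  }
  pb60 <- periodic_breathing(modulate(60))
  expect_true(pb60$flagged)
  expect_equal(pb60$period_s, 60, tolerance = 5 / 60)

  expect_false(periodic_breathing(resp_envelope(comp))$flagged)
  expect_false(periodic_breathing(modulate(20))$flagged)

  short <- resp_envelope(bed_series(comp$x[1:(80 * 300)],
                                    comp$t[1:(80 * 300)], comp$fs))
  expect_false(periodic_breathing(short)$evaluable)
})
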