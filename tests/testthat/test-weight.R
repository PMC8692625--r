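test_that("total weight is the calibrated channel sum", {
  t <- (0:79) / 80
  fr <- sensor_frame(t, cbind(100, 100, 50, 50)[rep(1, 80), ], units = "lbs")
  expect_equal(total_weight(fr)$x, rep(300, 80))
  fr0 <- sensor_frame(t, matrix(0, 80, 4), units = "lbs")
  expect_equal(total_weight(fr0)$x, rep(0, 80))
  cal <- calibration_model(c(1, 1, 1))
  expect_error(total_weight(fr, cal), "channel count")
})

test_that("total weight is invariant to load position", {
  pl <- simulate_placements(load_lbs = 25, n_positions = 5, seed = 4)
  cal <- fit_joint_calibration(pl$frames, known_load = 25)
  tots <- vapply(pl$frames, function(f) mean(total_weight(f, cal)$x),
                 numeric(1))
  expect_lt(sd(tots) / 25, 0.005)
})

test_that("step detection resolves the aliquot staircase", {
  a <- simulate_aliquot_test(130, n_aliquots = 5, noise_sd = 0, seed = 3)
  ev <- detect_weight_events(total_weight(a$frame), min_step_lbs = 0.02)
  expect_equal(nrow(ev), 5)
  expect_equal(ev$delta_lbs, rep(0.033, 5), tolerance = 1e-6)

  # with sensor noise, 0.03 lbs steps remain detectable
  an <- simulate_aliquot_test(130, aliquot_lbs = 0.03, n_aliquots = 5,
                              noise_sd = 0.005, seed = 13)
  evn <- detect_weight_events(total_weight(an$frame), min_step_lbs = 0.02)
  expect_equal(nrow(evn), 5)
  expect_true(all(abs(evn$delta_lbs - 0.03) <= 0.005))
})

test_that("entry and exit events cancel; ramps yield no events", {
  p <- person_spec(150, entry_s = 60, exit_s = 200)
  s <- simulate_session(p, noise_sd = 0.02, duration_s = 300, seed = 42)
  ev <- detect_weight_events(total_weight(s$frame))
  expect_equal(nrow(ev), 2)
  expect_equal(sum(ev$delta_lbs), 0, tolerance = 0.5)
  expect_equal(abs(ev$time_s - c(60, 200)) < 2, c(TRUE, TRUE))

  # a continuous ramp has no settled plateaus
  t <- (0:(80 * 120 - 1)) / 80
  ramp <- bed_series(120 + t * 0.5, t, 80)
  expect_equal(nrow(detect_weight_events(ramp, min_step_lbs = 5)), 0)
})

test_that("time reversal negates event deltas", {
  a <- simulate_aliquot_test(130, aliquot_lbs = 2, n_aliquots = 3,
                             interval_s = 25, noise_sd = 0.01, seed = 9)
  tot <- total_weight(a$frame)
  ev <- detect_weight_events(tot, min_step_lbs = 1)
  rev_tot <- bed_series(rev(tot$x), tot$t, tot$fs)
  ev_rev <- detect_weight_events(rev_tot, min_step_lbs = 1)
  expect_equal(sort(ev_rev$delta_lbs), sort(-ev$delta_lbs), tolerance = 0.05)
})

test_that("two-person weights are recovered at all protocol intervals", {
  p1 <- person_spec(160); p2 <- person_spec(125)
  for (iv in c(30, 15, 10, 5)) {
    sim <- simulate_simultaneity(p1, p2, interval_s = iv, seed = 5)
    ev <- detect_weight_events(total_weight(sim$frame))
    at <- attribute_persons(ev)
    w <- sort(c(at$P1$weight_lbs, at$P2$weight_lbs))
    expect_equal(w, c(125, 160), tolerance = 0.01)
  }
})

test_that("attribution handles one person, labels and ambiguity", {
  # single person: one cluster, P2 absent
  ev1 <- data.frame(time_s = c(10, 200), delta_lbs = c(150.1, -149.9),
                    pre_plateau_lbs = 0, post_plateau_lbs = 0,
                    person_label = "unassigned")
  at1 <- attribute_persons(ev1)
  expect_null(at1$P2)
  expect_equal(at1$P1$weight_lbs, 150, tolerance = 0.01)

  # sub-person magnitudes are objects, excluded from attribution
  ev2 <- rbind(ev1, data.frame(time_s = 100, delta_lbs = 8,
                               pre_plateau_lbs = 0, post_plateau_lbs = 0,
                               person_label = "unassigned"))
  at2 <- attribute_persons(ev2)
  expect_equal(at2$events$person_label[at2$events$time_s == 100], "object")

  # three distinct magnitudes cannot be two persons
  ev3 <- data.frame(time_s = c(1, 2, 3), delta_lbs = c(80, 150, 220),
                    pre_plateau_lbs = 0, post_plateau_lbs = 0,
                    person_label = "unassigned")
  expect_error(attribute_persons(ev3), "ambiguous")

  # label permutation only when entry order swaps
  p1 <- person_spec(160); p2 <- person_spec(125)
  sa <- simulate_simultaneity(p1, p2, interval_s = 20, seed = 7)
  sb <- simulate_simultaneity(p2, p1, interval_s = 20, seed = 7)
  wa <- attribute_persons(detect_weight_events(total_weight(sa$frame)))
  wb <- attribute_persons(detect_weight_events(total_weight(sb$frame)))
  expect_equal(sort(c(wa$P1$weight_lbs, wa$P2$weight_lbs)),
               sort(c(wb$P1$weight_lbs, wb$P2$weight_lbs)), tolerance = 0.01)
})

test_that("occupancy classification applies threshold and hysteresis", {
  # 12 of 24 hours in bed at 1 Hz resolution
  t <- 0:(86400 - 1)
  x <- ifelse(t >= 21600 & t < 64800, 270, 120)
  oc <- occupancy(bed_series(x, t, 1), empty_bed_lbs = 120)
  expect_equal(mean(oc$epochs$in_bed), 0.5, tolerance = 0.001)
  expect_equal(nrow(oc$intervals), 1)

  # never occupied
  oc0 <- occupancy(bed_series(rep(120, 3600), 0:3599, 1),
                   empty_bed_lbs = 120)
  expect_equal(sum(oc0$epochs$in_bed), 0)

  # hysteresis: dip to threshold - 2 does not end the interval
  x2 <- rep(120, 3600)
  x2[1000:2000] <- 175
  x2[1400:1420] <- 168 # inside the 5 lbs hysteresis band
  oc2 <- occupancy(bed_series(x2, 0:3599, 1), empty_bed_lbs = 120,
                   person_threshold_lbs = 50)
  expect_equal(nrow(oc2$intervals), 1)

  expect_error(occupancy(bed_series(x2, 0:3599, 1)), "calibration error")
})

test_that("occupancy endpoints match simulator truth", {
  p <- person_spec(150, entry_s = 60, exit_s = 400)
  s <- simulate_session(p, noise_sd = 0.02, duration_s = 600, seed = 42)
  oc <- occupancy(total_weight(s$frame), empty_interval_s = c(0, 50))
  expect_equal(nrow(oc$intervals), 1)
  expect_lt(abs(oc$intervals$start_s - 60), 2)
  expect_lt(abs(oc$intervals$end_s - 400), 2)
})

test_that("daily weight is the median magnitude of the day's events", {
  ev <- data.frame(time_s = c(100, 30000), delta_lbs = c(150.2, -149.8),
                   pre_plateau_lbs = 0, post_plateau_lbs = 0,
                   person_label = "P1")
  dw <- daily_weight(ev)
  expect_equal(dw$weight_lbs, 150)
  expect_equal(dw$n_events, 2)

  dw1 <- daily_weight(ev[1, ])
  expect_equal(dw1$weight_lbs, 150.2)

  # no events: day absent, not zero
  dw0 <- daily_weight(ev[0, ])
  expect_equal(nrow(dw0), 0)
})

test_that("water-aliquot mass converts to the printed pound value", {
  expect_equal(round(ml_water_to_lbs(15), 3), 0.033)
})
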