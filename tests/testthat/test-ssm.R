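test_that("the RTS smoother equals the dense joint-Gaussian oracle", {
  A <- matrix(c(0.9, 0.1, -0.1, 0.9), 2, 2)
  set.seed(99)
  C <- matrix(rnorm(4), 2, 2)
  Q <- diag(2) * 0.3
  rdiag <- c(0.2, 0.5)
  mu0 <- c(0, 0); P0 <- diag(2)
  for (T_ in c(20, 50)) {
    d <- sim_ssm(T_, A, C, Q, rdiag, mu0, P0, seed = T_)
    par <- ssm_params(A, C, Q, rdiag, mu0, P0, n_sources = 1, state_dim = 2)
    sm <- kalman_smooth(d$y, par)
    oracle <- dense_oracle(d$y, A, C, Q, rdiag, mu0, P0)
    expect_lt(max(abs(sm$means - oracle$means)), 1e-8)
    expect_equal(sm$loglik, oracle$loglik, tolerance = 1e-10)
  }
})

test_that("white-noise log-likelihood matches the closed form", {
  # A = 0 and P0 = Q make every observation iid N(0, C Q C' + R)
  set.seed(12)
  T_ <- 300
  r <- 0.4
  y <- matrix(rnorm(T_ * 2, 0, sqrt(1 + r)), T_, 2)
  par <- ssm_params(matrix(0, 2, 2), diag(2), diag(2), c(r, r),
                    c(0, 0), diag(2), n_sources = 1, state_dim = 2)
  sm <- kalman_smooth(y, par)
  ll_closed <- sum(stats::dnorm(y, 0, sqrt(1 + r), log = TRUE))
  expect_equal(sm$loglik, ll_closed, tolerance = 1e-8)
})

test_that("degenerate observation model reproduces the data; gaps are skipped", {
  set.seed(5)
  T_ <- 100
  y <- matrix(cumsum(rnorm(T_, 0, 0.1)), T_, 1)
  par <- ssm_params(matrix(1, 1, 1), matrix(1, 1, 1), matrix(0.01, 1, 1),
                    1e-12, 0, matrix(1, 1, 1), n_sources = 1, state_dim = 1)
  sm <- kalman_smooth(y, par)
  expect_equal(as.numeric(sm$means), as.numeric(y), tolerance = 1e-4)

  y2 <- y; y2[40:45, ] <- NA
  sm2 <- kalman_smooth(y2, par)
  expect_equal(nrow(sm2$means), T_)
  expect_true(all(is.finite(sm2$means)))
  expect_true(sm2$loglik < sm$loglik) # fewer observed rows
})

test_that("ssm_params validates covariances and stability", {
  expect_error(ssm_params(matrix(1.1, 1, 1), matrix(1, 1, 1),
                          matrix(1, 1, 1), 1, 0, matrix(1, 1, 1),
                          n_sources = 1, state_dim = 1), "spectral radius")
  expect_error(ssm_params(matrix(0.5, 1, 1), matrix(1, 1, 1),
                          matrix(1, 1, 1), 0, 0, matrix(1, 1, 1),
                          n_sources = 1, state_dim = 1), "> 0")
})

test_that("EM increases the likelihood and reaches the truth's level", {
  A <- matrix(0, 4, 4)
  A[1:2, 1:2] <- 0.98 * rot2(0.15)
  A[3:4, 3:4] <- 0.98 * rot2(0.3)
  set.seed(61)
  C <- matrix(rnorm(8), 2, 4) # 2 channels x 4 states
  Q <- diag(4) * 0.05
  rdiag <- c(0.1, 0.1)
  d <- sim_ssm(1500, A, C, Q, rdiag, rep(0, 4), diag(4), seed = 61)
  fit <- fit_em(d$y, n_sources = 2, state_dim = 2, dt = 0.2, seed = 1,
                restarts = 1, max_iter = 80)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8 * 1500 - 1e-6))
  truth_par <- ssm_params(A, C, Q, rdiag, rep(0, 4), diag(4))
  ll_truth <- kalman_smooth(d$y, truth_par)$loglik
  expect_gte(fit$loglik, ll_truth - 1e-3 * 1500)
})

test_that("duplicated channels get identical mixing rows", {
  s <- simulate_session(person_spec(150, resp_rate = 14), noise_sd = 0.01,
                        duration_s = 180, seed = 71)
  rc <- resp_channels(s$frame)
  Y <- rc$channels[seq(1, nrow(rc$channels), by = 16), ]
  Ydup <- cbind(Y, Y[, 1]) # channel 5 duplicates channel 1
  fit <- fit_em(Ydup, n_sources = 2, dt = 0.2, seed = 1, restarts = 1,
                max_iter = 40)
  expect_equal(fit$params$mixing[1, ], fit$params$mixing[5, ],
               tolerance = 1e-6)
})

test_that("a single source leaves the second component nearly empty", {
  s <- simulate_session(person_spec(150, resp_rate = 14,
                                    projection = c(0.4, 0.3, 0.2, 0.1)),
                        noise_sd = 0.01, duration_s = 300, seed = 72)
  expect_warning(
    dm <- demix(resp_channels(s$frame), seed = 1, restarts = 1,
                max_iter = 100),
    "collinear")
  v <- dm$source_sd^2
  expect_lt(min(v) / sum(v), 0.05)
})

test_that("two sleepers demix to their true respiratory sources", {
  s <- two_sleeper_session(seed = 11)
  dm <- demix(resp_channels(s$frame), seed = 1, restarts = 1, max_iter = 150)
  truth <- truth_sources_decimated(s)
  expect_gte(paired_min_cor(dm$sources, truth), 0.9)

  # gauge: channel reordering only permutes/flips the recovered sources
  rc <- resp_channels(s$frame)
  perm <- c(3, 1, 4, 2)
  rc2 <- sensor_frame(rc$timestamps, rc$channels[, perm],
                      units = rc$units, nominal_rate = rc$nominal_rate)
  dm2 <- demix(rc2, seed = 1, restarts = 1, max_iter = 150)
  cc <- abs(cor(dm$sources, dm2$sources))
  expect_gte(max(min(cc[1, 1], cc[2, 2]), min(cc[1, 2], cc[2, 1])), 0.99)
})

test_that("identical-rate identical-projection sources raise the ambiguity warning", {
  p <- person_spec(150, resp_rate = 15, projection = c(0.3, 0.3, 0.2, 0.2))
  s <- simulate_session(list(p, p), noise_sd = 0.01, duration_s = 180,
                        seed = 73)
  expect_warning(
    demix(resp_channels(s$frame), seed = 1, restarts = 1, max_iter = 30),
    "collinear")
})

test_that("mixing recovery: true projection directions within 5 degrees", {
  s <- two_sleeper_session(seed = 19, duration_s = 960) # T = 4800 at 5 Hz
  dm <- demix(resp_channels(s$frame), seed = 1, restarts = 1, max_iter = 150)
  M <- dm$mixing
  truth <- s$truth$mixing
  ang <- function(u, v) {
    c1 <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
    acos(pmin(c1, 1)) * 180 / pi
  }
  # match columns by best correlation of sources, then compare directions
  a11 <- ang(M[, 1], truth[, 1]) + ang(M[, 2], truth[, 2])
  a12 <- ang(M[, 1], truth[, 2]) + ang(M[, 2], truth[, 1])
  expect_lt(min(a11, a12) / 2, 5)
})

test_that("peak-timing error is zero for identity and exact for pure shifts", {
  fs <- 10
  t <- (0:(fs * 300 - 1)) / fs
  src <- sin(2 * pi * t / 4)
  pk <- t[find_peaks_in_test(src)]
  pe <- peak_timing_error(bed_series(src, t, fs), pk)
  expect_equal(pe$mean_abs_s, 0, tolerance = 1e-6)
  expect_true(pe$evaluable)

  shift <- round(0.2 * fs)
  src2 <- c(rep(0, shift), src[1:(length(src) - shift)])
  pe2 <- peak_timing_error(bed_series(src2, t, fs), pk)
  expect_equal(pe2$mean_abs_s, 0.2, tolerance = 0.02)
  expect_lt(pe2$sd_abs_s, 0.02)

  expect_false(peak_timing_error(bed_series(src, t, fs), numeric(0))$evaluable)
})

test_that("demixed sources match their own reference better than the other's", {
  s <- two_sleeper_session(seed = 23)
  dm <- demix(resp_channels(s$frame), seed = 1, restarts = 1, max_iter = 150)
  truth <- truth_sources_decimated(s)
  cc <- abs(cor(dm$sources, truth))
  asg <- if (cc[1, 1] + cc[2, 2] >= cc[1, 2] + cc[2, 1]) c(1, 2) else c(2, 1)
  for (k in 1:2) {
    own <- s$truth$breath_peaks[[asg[k]]]
    other <- s$truth$breath_peaks[[setdiff(1:2, asg[k])]]
    sk <- bed_series(dm$sources[, k], dm$t, dm$fs)
    e_own <- peak_timing_error(sk, own)
    e_other <- peak_timing_error(sk, other)
    expect_lt(e_own$mean_abs_s, e_other$mean_abs_s)
  }
})
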