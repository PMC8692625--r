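# Shared fixtures, generated in code at test time.

# a standard two-sleeper session with well-separated projections and rates
two_sleeper_session <- function(seed, duration_s = 600, rr1 = 12, rr2 = 17) {
  p1 <- person_spec(160, projection = c(0.45, 0.3, 0.15, 0.1),
                    resp_rate = rr1, resp_amplitude = 0.5)
  p2 <- person_spec(125, projection = c(0.1, 0.15, 0.3, 0.45),
                    resp_rate = rr2, resp_amplitude = 0.45)
  simulate_session(list(p1, p2), noise_sd = 0.01, duration_s = duration_s,
                   seed = seed)
}

# truth respiratory sources band-passed and decimated to the demix grid
truth_sources_decimated <- function(sim, demix_fs = 5, fs = 80) {
  by <- as.integer(round(fs / demix_fs))
  dec <- seq(1, nrow(sim$truth$sources), by = by)
  apply(sim$truth$sources, 2, function(s)
    bandpass(s, 0.167, 1.5, fs = fs)[dec])
}

# best min paired |correlation| over the two source-to-truth assignments
paired_min_cor <- function(sources, truth) {
  cc <- abs(stats::cor(sources, truth))
  max(min(cc[1, 1], cc[2, 2]), min(cc[1, 2], cc[2, 1]))
}

# build a beat_series by hand (amplitude holds the energy scale: the square
# of the magnitude the analytics report)
make_beats <- function(times, magnitudes) {
  structure(data.frame(time_s = times, amplitude = magnitudes^2,
                       resp_phase = rep("unknown", length(times))),
            class = c("beat_series", "data.frame"))
}

# rate-epoch data.frame on the 30 s grid from plain rates
make_epochs <- function(rates, start_s = 0, valid = TRUE) {
  data.frame(epoch_start_s = start_s + 30 * (seq_along(rates) - 1),
             rate_bpm = rates,
             n_peaks_used = ifelse(is.na(rates), 0L, 10L),
             valid = valid & !is.na(rates),
             reason_invalid = rep("", length(rates)))
}

# 2x2 rotation by angle theta (radians)
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# simple local-maxima indices for clean test signals
find_peaks_in_test <- function(x) {
  d <- diff(x)
  which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
}

# draw a trajectory + observations from a known linear-Gaussian model
sim_ssm <- function(T_, A, C, Q, rdiag, mu0, P0, seed) {
  set.seed(seed)
  k <- nrow(A); p <- nrow(C)
  x <- matrix(0, T_, k); y <- matrix(0, T_, p)
  xc <- mu0 + t(chol(P0)) %*% rnorm(k)
  cq <- t(chol(Q))
  for (t_ in seq_len(T_)) {
    if (t_ > 1) xc <- A %*% xc + cq %*% rnorm(k)
    x[t_, ] <- xc
    y[t_, ] <- C %*% xc + rnorm(p, 0, sqrt(rdiag))
  }
  list(x = x, y = y)
}

# dense joint-Gaussian conditional mean and log-likelihood (brute force)
dense_oracle <- function(y, A, C, Q, rdiag, mu0, P0) {
  T_ <- nrow(y); k <- nrow(A); p <- nrow(C)
  idx <- function(t_) ((t_ - 1) * k + 1):(t_ * k)
  Ppr <- vector("list", T_)
  Ppr[[1]] <- P0
  for (t_ in 2:T_) Ppr[[t_]] <- A %*% Ppr[[t_ - 1]] %*% t(A) + Q
  Sig <- matrix(0, T_ * k, T_ * k)
  for (t_ in 1:T_) {
    Sig[idx(t_), idx(t_)] <- Ppr[[t_]]
    if (t_ < T_) {
      M <- Ppr[[t_]]
      for (s_ in (t_ + 1):T_) {
        M <- M %*% t(A)
        Sig[idx(t_), idx(s_)] <- M
        Sig[idx(s_), idx(t_)] <- t(M)
      }
    }
  }
  H <- matrix(0, T_ * p, T_ * k)
  for (t_ in 1:T_) H[((t_ - 1) * p + 1):(t_ * p), idx(t_)] <- C
  S <- H %*% Sig %*% t(H) + diag(rep(rdiag, T_))
  yv <- as.numeric(t(y))
  mu <- Sig %*% t(H) %*% solve(S, yv)
  ll <- -0.5 * (T_ * p * log(2 * pi) +
                  as.numeric(determinant(S)$modulus) +
                  sum(yv * solve(S, yv)))
  list(means = matrix(mu, T_, k, byrow = TRUE), loglik = ll)
}

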