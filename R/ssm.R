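#' Parameters of the linear-Gaussian state-space demixing model
#'
#' Each latent respiratory source is a 2-dimensional stochastic damped
#' harmonic oscillator (position + velocity analogue via a damped rotation);
#' the sources are stacked block-diagonally and mixed into the channels by a
#' linear observation operator with additive per-sensor (diagonal) Gaussian
#' noise:
#' \deqn{x_t = A x_{t-1} + w_t, \quad w_t \sim N(0, Q)}
#' \deqn{y_t = C x_t + v_t, \quad v_t \sim N(0, R)}
#'
#' @param transition state-dynamics matrix `A` (block-diagonal per source);
#'   spectral radius must not exceed 1 (+1e-6).
#' @param mixing observation matrix `C` (n_channels x total state dim).
#' @param process_cov state-noise covariance `Q` (symmetric PSD).
#' @param obs_cov_diag diagonal of the sensor-noise covariance `R` (all > 0).
#' @param init_mean,init_cov initial-state distribution.
#' @param n_sources,state_dim source count and per-source state dimension.
#' @return An object of class `ssm_params`.
#' @export
ssm_params <- function(transition, mixing, process_cov, obs_cov_diag,
                       init_mean, init_cov, n_sources = 2, state_dim = 2) {
  k <- nrow(transition)
  stopifnot(ncol(transition) == k, ncol(mixing) == k,
            nrow(process_cov) == k, length(init_mean) == k,
            nrow(init_cov) == k, n_sources * state_dim == k)
  if (any(obs_cov_diag <= 0)) stop("observation noise variances must be > 0")
  sr <- max(Mod(eigen(transition, only.values = TRUE)$values))
  if (sr > 1 + 1e-6)
    stop(sprintf("transition spectral radius %.4f exceeds 1", sr))
  if (max(abs(process_cov - t(process_cov))) > 1e-8)
    stop("process covariance must be symmetric")
  structure(list(transition = transition, mixing = mixing,
                 process_cov = process_cov, obs_cov_diag = obs_cov_diag,
                 init_mean = init_mean, init_cov = init_cov,
                 n_sources = n_sources, state_dim = state_dim),
            class = "ssm_params")
}

#' @export
print.ssm_params <- function(x, ...) {
  cat(sprintf("<ssm_params> %d sources x %d states, %d channels\n",
              x$n_sources, x$state_dim, nrow(x$mixing)))
  cat("mixing (channels x states):\n"); print(round(x$mixing, 3))
  invisible(x)
}

#' Fixed-interval Kalman (RTS) smoother
#'
#' Runs the Kalman filter forward and the Rauch-Tung-Striebel smoother
#' backward, returning posterior state means and variances given the whole
#' observation sequence, plus the exact Gaussian log-likelihood. Rows of
#' `obs` containing NA are treated as missing (the correction step is
#' skipped).
#'
#' @param obs numeric matrix, T x n_channels.
#' @param params an [ssm_params()].
#' @return A list: `means` (T x k), `variances` (T x k pointwise posterior
#'   variances), `loglik`.
#' @export
kalman_smooth <- function(obs, params) {
  obs <- as.matrix(obs)
  stopifnot(inherits(params, "ssm_params"),
            ncol(obs) == nrow(params$mixing))
  ev <- eigen(params$process_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("process covariance is not positive semi-definite")
  r <- kalman_estep_cpp(obs, params$transition, params$mixing,
                        params$process_cov, params$obs_cov_diag,
                        params$init_mean, params$init_cov, FALSE)
  list(means = r$xs, variances = r$ps_var, loglik = r$loglik)
}

# block-diagonal index helper
blk_idx <- function(s, d) ((s - 1) * d + 1):(s * d)

# damped rotation block: oscillation at f Hz, amplitude decay rho per step
osc_block <- function(f, dt, rho) {
  th <- 2 * pi * f * dt
  rho * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# initial parameters: per-source mixing columns and fundamental frequencies
# from the cross-channel DFT pattern at the dominant spectral peaks (each
# sleeper's respiratory fundamental marks its own projection pattern);
# falls back to PCA loadings when distinct peaks cannot be found
init_ssm <- function(Y, n_sources, state_dim, dt, jitter = 0,
                     min_sep_hz = 0.03) {
  p <- ncol(Y)
  k <- n_sources * state_dim
  T_ <- nrow(Y)
  Yc <- scale(Y, scale = FALSE)
  Z <- stats::mvfft(Yc)
  nf <- floor(T_ / 2)
  fr <- (seq_len(nf) - 1) / (T_ * dt)
  pw <- rowSums(Mod(Z[seq_len(nf), , drop = FALSE])^2)
  pw[fr < 0.05] <- 0
  o <- order(pw, decreasing = TRUE)
  bins <- integer(0)
  for (b in o) {
    if (all(abs(fr[b] - fr[bins]) >= min_sep_hz)) bins <- c(bins, b)
    if (length(bins) == n_sources) break
  }
  U <- matrix(0, p, n_sources)
  freqs <- numeric(n_sources)
  for (s in seq_along(bins)) {
    z <- Z[bins[s], ]
    v <- Re(z / z[which.max(Mod(z))])
    nv <- sqrt(sum(v^2))
    if (nv > 0) U[, s] <- v / nv
    freqs[s] <- fr[bins[s]]
  }
  if (length(bins) < n_sources || any(colSums(abs(U)) == 0)) {
    sv <- svd(Yc, nu = 0, nv = n_sources)
    for (s in seq_len(n_sources)) {
      if (all(U[, s] == 0)) {
        U[, s] <- sv$v[, s]
        freqs[s] <- max(freqs[freqs > 0], 0.25, na.rm = TRUE) * (1 + 0.2 * s)
      }
    }
  }
  pcs <- Y %*% U
  if (jitter > 0) freqs <- freqs * exp(runif(n_sources, -jitter, jitter))
  freqs <- pmin(pmax(freqs, 0.05), 0.45 / dt)
  A <- matrix(0, k, k)
  Q <- matrix(0, k, k)
  C <- matrix(0, p, k)
  if (state_dim %% 2 != 0) stop("`state_dim` must be even (oscillator pairs)")
  n_osc <- state_dim / 2
  rho <- exp(-dt / 20) # ~20 s amplitude memory
  for (s in seq_len(n_sources)) {
    ii <- blk_idx(s, state_dim)
    vs <- var(pcs[, s])
    for (m in seq_len(n_osc)) {
      # harmonic stack: oscillator m at m x the fundamental frequency
      jj <- ii[(2 * m - 1):(2 * m)]
      A[jj, jj] <- osc_block(min(m * freqs[s], 0.45 / dt), dt, rho)
      Q[jj, jj] <- diag(2) * vs * (1 - rho^2) / m
      C[, jj[1]] <- U[, s] / m
    }
    if (jitter > 0)
      C[, ii[1]] <- C[, ii[1]] + rnorm(p, 0, jitter * 0.2)
  }
  rdiag <- pmax(apply(Y, 2, var) * 0.1, 1e-8)
  mu0 <- numeric(k)
  P0 <- diag(k) * max(apply(Y, 2, var))
  ssm_params(A, C, Q, rdiag, mu0, P0, n_sources, state_dim)
}

#' Fit the demixing state-space model by expectation-maximization
#'
#' Alternates the Kalman-smoother E-step (exact posterior sufficient
#' statistics) with closed-form M-step updates of the transition blocks, the
#' mixing operator, the (block-diagonal) process covariance and the diagonal
#' observation covariance, until the log-likelihood gain falls below `tol`.
#' The log-likelihood is non-decreasing by construction; a decrease beyond
#' numerical slack raises an internal error. Initialization is seeded and
#' deterministic; `restarts` seeded jittered restarts are run and the best
#' log-likelihood kept.
#'
#' @param obs numeric matrix, T x n_channels, already bandpassed to the
#'   respiratory band (duration >= 60 s recommended).
#' @param n_sources number of latent sources (2 for a shared bed).
#' @param state_dim state dimension per source.
#' @param max_iter,tol EM stopping rule (relative log-likelihood change).
#' @param seed integer seed for restart jitter.
#' @param dt sample interval of `obs`, seconds.
#' @param restarts number of jittered initializations.
#' @param estimate_transition estimate the transition blocks (default) or
#'   keep them fixed at their initialization.
#' @return An object of class `ssm_fit`: `params`, `loglik_trace`,
#'   `converged`, `n_iter`.
#' @export
fit_em <- function(obs, n_sources = 2, state_dim = 2, max_iter = 200,
                   tol = 1e-6, seed = 1, dt, restarts = 3,
                   estimate_transition = TRUE) {
  Y <- as.matrix(obs)
  if (missing(dt)) stop("`dt` (sample interval of `obs`) is required")
  best <- NULL
  with_seed(seed, function() {
    for (r in seq_len(restarts)) {
      par0 <- init_ssm(Y, n_sources, state_dim, dt,
                       jitter = if (r == 1) 0 else 0.2)
      fit <- tryCatch(
        em_run(Y, par0, max_iter, tol, estimate_transition),
        error = function(e) NULL)
      if (!is.null(fit) &&
          (is.null(best) || fit$loglik > best$loglik)) best <<- fit
    }
  })
  if (is.null(best)) stop("EM failed for all restarts")
  structure(list(params = best$params, loglik_trace = best$trace,
                 loglik = best$loglik, converged = best$converged,
                 n_iter = length(best$trace)), class = "ssm_fit")
}

#' @export
print.ssm_fit <- function(x, ...) {
  cat(sprintf("<ssm_fit> %d sources; %d EM iterations; loglik %.2f (%s)\n",
              x$params$n_sources, x$n_iter, x$loglik,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' @export
logLik.ssm_fit <- function(object, ...) {
  structure(object$loglik, class = "logLik",
            df = length(object$params$mixing) +
              length(object$params$transition))
}

em_run <- function(Y, par, max_iter, tol, estimate_transition) {
  T_ <- nrow(Y)
  d <- par$state_dim; ns <- par$n_sources
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    e <- kalman_estep_cpp(Y, par$transition, par$mixing, par$process_cov,
                          par$obs_cov_diag, par$init_mean, par$init_cov, TRUE)
    ll <- e$loglik
    if (it > 1 && ll < ll_prev - 1e-8 * T_ - 1e-6)
      stop(sprintf("EM log-likelihood decreased at iteration %d (%.6g -> %.6g)",
                   it, ll_prev, ll))
    trace <- c(trace, ll)
    if (it > 1 && abs(ll - ll_prev) < tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    # ---- M-step ----
    A <- par$transition
    Q <- par$process_cov
    for (s in seq_len(ns)) {
      ii <- blk_idx(s, d)
      S00b <- e$S00[ii, ii, drop = FALSE]
      S10b <- e$S10[ii, ii, drop = FALSE]
      S11b <- e$S11[ii, ii, drop = FALSE]
      Ab <- if (estimate_transition) {
        reg <- diag(d) * (1e-10 * max(diag(S00b)) + 1e-300)
        t(solve(S00b + reg, t(S10b)))
      } else A[ii, ii]
      # contract toward the unit disc if estimation overshoots
      sr <- max(Mod(eigen(Ab, only.values = TRUE)$values))
      if (sr > 1) Ab <- Ab / (sr + 1e-9)
      Qb <- (S11b - Ab %*% t(S10b) - S10b %*% t(Ab) +
               Ab %*% S00b %*% t(Ab)) / (T_ - 1)
      Qb <- (Qb + t(Qb)) / 2
      dq <- diag(Qb)
      if (any(dq < 1e-12)) Qb <- Qb + diag(d) * 1e-12
      A[ii, ii] <- Ab
      Q[ii, ii] <- Qb
    }
    regx <- diag(nrow(e$Sxx)) * (1e-10 * max(diag(e$Sxx)) + 1e-300)
    C <- t(solve(e$Sxx + regx, t(e$Syx)))
    rdiag <- (e$syy - 2 * rowSums(C * e$Syx) +
                rowSums((C %*% e$Sxx) * C)) / e$nobs
    rdiag <- pmax(rdiag, 1e-12)
    par <- ssm_params(A, C, Q, rdiag, e$x1s, e$P1s, ns, d)
  }
  list(params = par, trace = trace, loglik = trace[length(trace)],
       converged = converged)
}

#' Demix two respiratory sources from a shared bed
#'
#' Decimates the respiratory-band channels to `demix_fs` (the band is below
#' 1.5 Hz, so 10 Hz retains it comfortably and makes estimation fast), fits
#' the state-space model by [fit_em()], Kalman-smooths, and reduces each
#' source to its scalar respiratory coordinate normalised to unit variance
#' (the amplitude gauge is not identifiable; label order is arbitrary). A
#' warning is raised when the two mixing columns are nearly collinear (the
#' unidentifiable identical-projection case).
#'
#' @param channels a [sensor_frame()] of respiratory-band channels (see
#'   [resp_channels()]), or a plain T x p matrix with `fs` supplied.
#' @param fs sampling rate of a plain-matrix input.
#' @param n_sources number of sources.
#' @param demix_fs internal decimated rate in Hz (the respiratory band
#'   tops out at 1.5 Hz, so 5 Hz retains it comfortably).
#' @param seed seed for EM restarts.
#' @param ... passed to [fit_em()].
#' @return An object of class `bed_demix`: `sources` (T x n_sources matrix on
#'   the decimated time base, unit variance), `source_var` (posterior
#'   variances, diagonal approximation), `source_sd` (pre-normalisation
#'   scales), `t` (times), `fs`, `fit` (the [fit_em()] result).
#' @export
demix <- function(channels, fs = NULL, n_sources = 2, demix_fs = 5,
                  seed = 1, ...) {
  if (inherits(channels, "sensor_frame")) {
    Y <- channels$channels
    t <- channels$timestamps
    fs <- frame_fs(channels)
  } else {
    Y <- as.matrix(channels)
    if (is.null(fs)) stop("`fs` required for matrix input")
    t <- (seq_len(nrow(Y)) - 1) / fs
  }
  dec_fac <- max(1L, as.integer(round(fs / demix_fs)))
  sel <- seq(1, nrow(Y), by = dec_fac)
  Yd <- Y[sel, , drop = FALSE]
  td <- t[sel]
  dt <- dec_fac / fs
  fit <- fit_em(Yd, n_sources = n_sources, dt = dt, seed = seed, ...)
  d <- fit$params$state_dim
  # scalar respiratory coordinate of each source: its block's state
  # combination as seen through the leading direction of its mixing block
  wts <- lapply(seq_len(n_sources), function(s) {
    B <- fit$params$mixing[, blk_idx(s, d), drop = FALSE]
    as.numeric(t(B) %*% svd(B)$u[, 1])
  })
  M <- vapply(seq_len(n_sources), function(s) {
    as.numeric(fit$params$mixing[, blk_idx(s, d), drop = FALSE] %*% wts[[s]])
  }, numeric(ncol(Yd)))
  collinear <- FALSE
  if (n_sources == 2) {
    cthe <- abs(sum(M[, 1] * M[, 2])) /
      (sqrt(sum(M[, 1]^2)) * sqrt(sum(M[, 2]^2)))
    collinear <- is.finite(cthe) && cthe > 0.99
    if (collinear)
      warning("mixing columns nearly collinear: sources are not identifiable (identical projections?)")
  }
  sm <- kalman_smooth(Yd, fit$params)
  S <- vapply(seq_len(n_sources), function(s) {
    as.numeric(sm$means[, blk_idx(s, d), drop = FALSE] %*% wts[[s]])
  }, numeric(nrow(Yd)))
  # pointwise variance under a diagonal posterior approximation
  V <- vapply(seq_len(n_sources), function(s) {
    as.numeric(sm$variances[, blk_idx(s, d), drop = FALSE] %*% (wts[[s]]^2))
  }, numeric(nrow(Yd)))
  if (collinear) {
    # both state blocks project onto one physical direction (one sleeper's
    # fundamental plus its harmonics): re-gauge in channel space so source 1
    # carries the common direction and source 2 only the orthogonal residual
    Z <- 0
    for (s in seq_len(n_sources))
      Z <- Z + sm$means[, blk_idx(s, d), drop = FALSE] %*%
        t(fit$params$mixing[, blk_idx(s, d), drop = FALSE])
    sv <- svd(Z, nu = 0, nv = n_sources)
    S <- Z %*% sv$v
    M <- sv$v
  }
  sds <- apply(S, 2, sd)
  sds[sds == 0] <- 1
  S <- sweep(S, 2, sds, `/`)
  V <- sweep(V, 2, sds^2, `/`)
  # sign gauge: a respiratory waveform has a brisk inspiratory upstroke and
  # a shallow expiratory decay, i.e. positive skew; orient each source so
  # inspiration points up
  for (s in seq_len(ncol(S))) {
    if (mean(S[, s]^3) < 0) {
      S[, s] <- -S[, s]
      M[, s] <- -M[, s]
    }
  }
  structure(list(sources = S, source_var = V, source_sd = sds, t = td,
                 fs = 1 / dt, fit = fit, mixing = M), class = "bed_demix")
}

#' @export
print.bed_demix <- function(x, ...) {
  cat(sprintf("<bed_demix> %d sources over %.1f s @ %g Hz; EM loglik %.2f\n",
              ncol(x$sources), diff(range(x$t)), x$fs, x$fit$loglik))
  invisible(x)
}

#' @export
plot.bed_demix <- function(x, ...) {
  op <- par(mfrow = c(ncol(x$sources), 1), mar = c(2, 4, 1, 1))
  on.exit(par(op))
  for (s in seq_len(ncol(x$sources)))
    plot(x$t, x$sources[, s], type = "l", ylab = sprintf("source %d", s), ...)
  invisible(x)
}

#' Breath-peak timing error between a demixed source and a reference
#'
#' Matches each reference peak to the nearest source peak within half the
#' median reference breath period and summarises the absolute offsets.
#'
#' @param source a demixed source as a [bed_series()], or a numeric vector
#'   with `fs` given.
#' @param reference_peaks reference breath-peak times in seconds (>= 10 for a
#'   stable summary).
#' @param fs sampling rate for plain numeric `source`.
#' @return A list: `mean_abs_s`, `sd_abs_s`, `n_matched`, `n_unmatched`,
#'   `evaluable`.
#' @export
peak_timing_error <- function(source, reference_peaks, fs = NULL) {
  if (!inherits(source, "bed_series")) {
    if (is.null(fs)) stop("`fs` required for numeric input")
    source <- bed_series(source, (seq_along(source) - 1) / fs, fs)
  }
  if (length(reference_peaks) < 2 || length(source$x) < 5)
    return(list(mean_abs_s = NA_real_, sd_abs_s = NA_real_, n_matched = 0,
                n_unmatched = length(reference_peaks), evaluable = FALSE))
  period <- median(diff(sort(reference_peaks)))
  sp <- find_breath_peaks(source, steady = NULL,
                          min_spacing_s = max(60 / 40, period / 2))
  if (!length(sp))
    return(list(mean_abs_s = NA_real_, sd_abs_s = NA_real_, n_matched = 0,
                n_unmatched = length(reference_peaks), evaluable = FALSE))
  err <- vapply(reference_peaks, function(rp) {
    d <- abs(sp - rp)
    m <- min(d)
    if (m <= period / 2) m else NA_real_
  }, numeric(1))
  matched <- err[!is.na(err)]
  list(mean_abs_s = mean(matched), sd_abs_s = sd(matched),
       n_matched = length(matched), n_unmatched = sum(is.na(err)),
       evaluable = length(matched) >= 10)
}
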