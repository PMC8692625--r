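#' Per-channel respiratory signals
#'
#' Bandpasses each calibrated channel to the respiratory band (0.167-1.5 Hz,
#' i.e. 10-90 breaths/min), zero phase.
#'
#' @param frame a [sensor_frame()].
#' @param cal optional [calibration_model()] applied first when the frame is
#'   in raw digitizer units.
#' @param low_hz,high_hz band edges in Hz.
#' @return A [sensor_frame()] of filtered channels.
#' @export
resp_channels <- function(frame, cal = NULL, low_hz = 0.167, high_hz = 1.5) {
  if (!is.null(cal)) frame <- apply_calibration(frame, cal)
  fs <- frame_fs(frame)
  ch <- apply(frame$channels, 2, bandpass, low_hz = low_hz, high_hz = high_hz,
              fs = fs)
  sensor_frame(frame$timestamps, ch, units = frame$units, nominal_rate = fs)
}

#' Sliding-window PCA respiratory composite
#'
#' Combines the per-channel respiratory signals into a single source signal:
#' within each 12.5 s window the channel covariance is computed, the leading
#' principal-component loading vector (unit norm) is taken, and the channels
#' are projected onto it. The loading sign is chosen so the highest-variance
#' channel loads positively (continuity across windows); adjacent windows are
#' crossfaded over 0.5 s to avoid steps. A zero-variance window carries the
#' previous window's loadings forward.
#'
#' @param channels a [sensor_frame()] from [resp_channels()] (>= 2 channels).
#' @param window_s PCA window length in seconds.
#' @param crossfade_s boundary crossfade in seconds.
#' @return A `bed_composite` (a [bed_series()] with a `window_weights`
#'   attribute: one unit-norm loading vector per window).
#' @export
pca_composite <- function(channels, window_s = 12.5, crossfade_s = 0.5) {
  stopifnot(inherits(channels, "sensor_frame"))
  X <- channels$channels
  fs <- frame_fs(channels)
  n <- nrow(X); C <- ncol(X)
  if (C < 2) stop("PCA compositing needs at least 2 channels")
  w <- as.integer(round(window_s * fs))
  if (w < 4) stop("window too short")
  n_win <- ceiling(n / w)
  W <- matrix(NA_real_, n_win, C)
  v_prev <- rep(1 / sqrt(C), C)
  out <- numeric(n)
  nf <- as.integer(round(crossfade_s * fs))
  for (k in seq_len(n_win)) {
    i0 <- (k - 1L) * w + 1L
    i1 <- min(n, k * w)
    Xw <- X[i0:i1, , drop = FALSE]
    vr <- apply(Xw, 2, var)
    if (max(vr) < .Machine$double.eps) {
      v <- v_prev
    } else {
      cv <- stats::cov(Xw)
      e <- eigen(cv, symmetric = TRUE)
      v <- e$vectors[, 1]
      if (v[which.max(vr)] < 0) v <- -v
    }
    W[k, ] <- v
    seg <- as.numeric(X[i0:i1, , drop = FALSE] %*% v)
    if (k > 1 && nf > 1 && length(seg) > nf) {
      prev_seg <- as.numeric(X[i0:(i0 + nf - 1L), , drop = FALSE] %*% v_prev)
      alpha <- seq(0, 1, length.out = nf)
      seg[seq_len(nf)] <- (1 - alpha) * prev_seg + alpha * seg[seq_len(nf)]
    }
    out[i0:i1] <- seg
    v_prev <- v
  }
  res <- bed_series(out, channels$timestamps, fs)
  attr(res, "window_weights") <- W
  attr(res, "window_s") <- window_s
  class(res) <- c("bed_composite", class(res))
  res
}

#' Breath-peak detection within steady regions
#'
#' Peaks are searched only inside movement-free (steady) regions, with a
#' minimum spacing of 1.5 s (fastest plausible rate, 40 breaths/min) and a
#' prominence of at least 25% of the region's amplitude scale.
#'
#' @param composite a [bed_series()] respiratory composite.
#' @param steady data.frame of steady regions (10 s minimum duration), from
#'   [steady_regions()]; `NULL` treats the whole signal as steady.
#' @param min_spacing_s minimum inter-peak spacing in seconds.
#' @param prominence_frac prominence threshold as a fraction of the region's
#'   amplitude scale (central 90% range / 2).
#' @return Numeric vector of peak times in seconds.
#' @export
find_breath_peaks <- function(composite, steady = NULL, min_spacing_s = 60 / 40,
                              prominence_frac = 0.25) {
  x <- composite$x; t <- composite$t; fs <- composite$fs
  regions <- if (is.null(steady))
    data.frame(start_s = t[1], end_s = t[length(t)]) else steady
  out <- numeric(0)
  for (i in seq_len(nrow(regions))) {
    sel <- which(t >= regions$start_s[i] & t <= regions$end_s[i])
    if (length(sel) < 5) next
    xr <- x[sel]
    scale <- diff(quantile(xr, c(0.05, 0.95), names = FALSE)) / 2
    if (scale <= 0) next
    # breathing slower than ~10/min has its fundamental below the 0.167 Hz
    # band edge, leaving harmonic double-humps per breath; the breath period
    # estimated from the autocorrelation (restricted to plausible-rate lags)
    # sets a half-period spacing floor that keeps one peak per breath
    spacing <- min_spacing_s
    lag_max <- min(length(xr) - 1L, as.integer(10 * fs))
    lo <- as.integer(min_spacing_s * fs)
    if (lag_max > 2 * lo) {
      a <- as.numeric(acf(xr, lag.max = lag_max, plot = FALSE,
                          demean = TRUE)$acf)
      pk_a <- find_peaks_prom(a, min_dist = lo, min_prom = 0.05)
      pk_a <- pk_a[pk_a > lo]
      if (length(pk_a)) {
        vals <- a[pk_a]
        strong <- pk_a[vals >= 0.9 * max(vals)]
        best <- strong[1] # fundamental, not a multiple of it
        spacing <- max(min_spacing_s, 0.5 * (best - 1) / fs)
      }
    }
    pk <- find_peaks_prom(xr, min_dist = spacing * fs,
                          min_prom = prominence_frac * scale)
    out <- c(out, t[sel[pk]])
  }
  sort(out)
}

# shared rate-epoch engine: rate from the median inter-peak interval in a
# centered moving window, evaluated on a fixed epoch grid
rate_epochs <- function(peaks, duration_s, epoch_s = 30, window_s = 300,
                        steady = NULL, max_unsteady_s = 45, min_peaks = 2) {
  ep <- seq(0, duration_s - 1e-9, by = epoch_s)
  res <- lapply(ep, function(e0) {
    cen <- e0 + epoch_s / 2
    lo <- max(0, cen - window_s / 2)
    hi <- min(duration_s, cen + window_s / 2)
    pk <- peaks[peaks >= lo & peaks <= hi]
    n <- length(pk)
    rate <- NA_real_
    valid <- TRUE; reason <- ""
    if (n < min_peaks) {
      valid <- FALSE; reason <- "too_few_peaks"
    } else {
      rate <- 60 / median(diff(pk))
    }
    if (valid && !is.null(steady)) {
      ov <- pmax(0, pmin(steady$end_s, hi) - pmax(steady$start_s, lo))
      unst <- (hi - lo) - sum(ov)
      if (unst > max_unsteady_s) { valid <- FALSE; reason <- "unsteady" }
    }
    data.frame(epoch_start_s = e0, rate_bpm = rate, n_peaks_used = n,
               valid = valid, reason_invalid = reason)
  })
  do.call(rbind, res)
}

#' Respiratory-rate epochs
#'
#' Every 30 s, the rate is 60 / median inter-peak interval within the
#' centered 5-min moving window. An epoch is invalid when the window holds
#' fewer than 2 peaks or more than 45 s of unsteady (movement-corrupted)
#' physiology.
#'
#' @param peaks breath-peak times from [find_breath_peaks()].
#' @param duration_s session length in seconds.
#' @param epoch_s epoch grid step.
#' @param window_s moving-window length.
#' @param steady optional steady-region data.frame for the validity rule.
#' @param max_unsteady_s maximum tolerated unsteady time per window.
#' @return A data.frame of rate epochs (`epoch_start_s`, `rate_bpm`,
#'   `n_peaks_used`, `valid`, `reason_invalid`).
#' @export
respiratory_rate <- function(peaks, duration_s, epoch_s = 30, window_s = 300,
                             steady = NULL, max_unsteady_s = 45) {
  rate_epochs(peaks, duration_s, epoch_s, window_s, steady, max_unsteady_s)
}

#' Respiratory amplitude envelope
#'
#' Moving RMS of the composite; the input to apnea detection and
#' periodic-breathing analysis.
#'
#' @param composite a [bed_series()].
#' @param window_s RMS window in seconds.
#' @return A [bed_series()].
#' @export
resp_envelope <- function(composite, window_s = 10) {
  bed_series(moving_rms(composite$x, window_s, composite$fs),
             composite$t, composite$fs)
}

#' Apnea detection and central/obstructive classification
#'
#' Low-variance regions lacking respiratory waveforms are found on a coarse
#' amplitude envelope (2 s moving RMS bridged by a 3 s moving maximum) as
#' runs below 50% of the local baseline; each run's boundaries are then
#' refined on the composite amplitude itself: the event starts where breath
#' activity (|composite| above 25% of the flanking amplitude scale) last
#' ceases and ends at the foot of the resumption breath's upstroke. Events
#' lasting more than 10 s are apneas (10 s or shorter are rejected). Kind:
#' central when residual effort is below 5% of the flanking amplitude,
#' obstructive in [5%, 50%), unclassified when no flanking baseline exists.
#'
#' @param composite a [bed_series()] respiratory composite.
#' @param min_duration_s events must exceed this duration (default 10 s).
#' @param threshold_frac coarse envelope threshold as a fraction of baseline.
#' @param central_frac central/obstructive split on residual effort fraction.
#' @param refine_frac amplitude-activity threshold for boundary refinement,
#'   as a fraction of the flanking amplitude scale.
#' @param rms_s,max_s coarse envelope window lengths in seconds.
#' @return A data.frame `start_s`, `duration_s`, `kind`,
#'   `effort_amplitude_fraction`.
#' @export
detect_apneas <- function(composite, min_duration_s = 10,
                          threshold_frac = 0.5, central_frac = 0.05,
                          refine_frac = 0.25, rms_s = 2, max_s = 3) {
  x <- composite$x; t <- composite$t; fs <- composite$fs
  env <- moving_max(moving_rms(x, rms_s, fs), max_s, fs)
  env2 <- moving_stat(x^2, rms_s, "mean", fs = fs) # short-time power
  # the beating heart leaks its fundamental (>= 0.8 Hz for rates above
  # ~50 bpm) into the respiratory band; measure that cardiac sub-band power
  # separately and subtract it, so a central apnea's residual effort is not
  # inflated by the heartbeat
  xh <- bandpass(x, 0.8, 1.49, fs = fs)
  env2h <- moving_stat(xh^2, rms_s, "mean", fs = fs)
  base0 <- median(env)
  low0 <- env < threshold_frac * base0
  r <- rle(low0)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  out <- data.frame(start_s = numeric(0), duration_s = numeric(0),
                    kind = character(0),
                    effort_amplitude_fraction = numeric(0))
  n <- length(x)
  for (k in cand) {
    i0 <- starts[k]; i1 <- ends[k]
    a <- t[i0]; b <- t[i1]
    # flanking breathing within +-60 s, excluding any low-envelope time
    fl <- which((t >= a - 60 & t < a) | (t > b & t <= b + 60))
    fl <- fl[!low0[fl]]
    kind_known <- length(fl) >= fs * 5
    if (!kind_known && !length(fl)) fl <- which(!low0)
    if (!length(fl)) next
    O <- median(env2[fl]) # breathing power level
    core <- i0:i1
    if (i1 - i0 > 4 * fs) core <- (i0 + 2 * fs):(i1 - 2 * fs)
    I <- median(env2[core]) # residual power inside the event
    if (!(I < O)) next
    # the processing chain is zero phase, so edge energy spreads
    # symmetrically: the half-level power crossing is the unbiased boundary
    th2 <- (I + O) / 2
    mid <- (i0 + i1) %/% 2L
    l <- mid
    while (l > 1 && env2[l] < th2) l <- l - 1L
    j <- mid
    while (j < n && env2[j] < th2) j <- j + 1L
    if (env2[l] < th2 || env2[j] < th2) next # ran off the signal
    cross <- function(ii, jj) { # linear interpolation of the crossing time
      t[ii] + (th2 - env2[ii]) / (env2[jj] - env2[ii]) * (t[jj] - t[ii])
    }
    a2 <- if (l < mid) cross(l, l + 1L) else t[l]
    b2 <- if (j > mid) cross(j, j - 1L) else t[j]
    # self-calibrated edge bias: fold the flanking breathing into a mean
    # cycle-power profile, rebuild each edge synthetically, and measure the
    # crossing offset the detector itself produces on it
    bias <- edge_bias(x, t, fl, I, th2, rms_s, fs)
    if (!is.null(bias)) {
      a2 <- a2 - bias[1]
      b2 <- b2 - bias[2]
    }
    dur <- b2 - a2
    if (dur <= min_duration_s) next
    core2 <- which(t >= a2 + 2 & t <= b2 - 2)
    if (!length(core2)) core2 <- core
    # band-edge ringing of the flanking breaths decays into the event
    # interior, so take the cleanest quartile of the interior power
    d2 <- pmax(env2 - env2h, 0)
    Ieff <- quantile(d2[core2], 0.25, names = FALSE)
    Oeff <- max(median(d2[fl]), .Machine$double.eps)
    effort <- sqrt(Ieff / Oeff) # amplitude scale
    kind <- if (!kind_known) "unclassified"
      else if (effort < central_frac) "central"
      else if (effort < threshold_frac) "obstructive"
      else next
    out <- rbind(out, data.frame(start_s = a2, duration_s = dur, kind = kind,
                                 effort_amplitude_fraction = effort))
  }
  rownames(out) <- NULL
  out
}

# Crossing bias of the half-level rule at an apnea edge, self-calibrated
# from the flanking breathing. Returns c(left_bias, right_bias) in seconds
# (detected minus true edge), or NULL when the flank has too few clean
# cycles to fold.
edge_bias <- function(x, t, fl, I, th2, rms_s, fs) {
  if (length(fl) < 10 * fs) return(NULL)
  pkt <- find_breath_peaks(bed_series(x[fl], t[fl], fs))
  if (length(pkt) < 4) return(NULL)
  Tm <- median(diff(pkt))
  L <- as.integer(round(Tm * fs))
  if (L < 4) return(NULL)
  flset <- logical(length(x)); flset[fl] <- TRUE
  prof <- NULL
  for (pk in pkt) {
    i0 <- which.min(abs(t - pk))
    if (i0 + L - 1L <= length(x) && all(flset[i0:(i0 + L - 1L)]))
      prof <- rbind(prof, x[i0:(i0 + L - 1L)]^2)
  }
  if (is.null(prof) || nrow(prof) < 3) return(NULL)
  p <- colMeans(prof)
  w <- as.integer(round(rms_s * fs))
  boxmean <- function(v) {
    o <- as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
    o[is.na(o)] <- mean(p)
    o
  }
  pad <- as.integer(12 * fs)
  # left edge: full cycles (peak-anchored) then residual power
  syn <- c(rep(p, 8), rep(I, pad))
  e2 <- boxmean(syn)
  jj <- length(syn) - 5L * as.integer(fs)
  while (jj > 1 && e2[jj] < th2) jj <- jj - 1L
  bias_l <- (jj - 8L * L) / fs
  # right edge: residual power, then resumption from the upstroke foot
  tau_r <- (L %/% 2L) + which.min(p[(L %/% 2L):L]) - 1L
  syn2 <- c(rep(I, pad), p[tau_r:L], rep(p, 8))
  e22 <- boxmean(syn2)
  jj2 <- 5L * as.integer(fs)
  while (jj2 < length(syn2) && e22[jj2] < th2) jj2 <- jj2 + 1L
  bias_r <- (jj2 - pad) / fs
  c(bias_l, bias_r)
}

#' Periodic-breathing (Cheyne-Stokes-like) flagging
#'
#' Computes the autocorrelation of the respiratory amplitude envelope and
#' flags periodic breathing when the first secondary autocorrelation peak is
#' at least 0.5 and occurs at a lag above `min_period_s` (crescendo-
#' decrescendo cycles longer than 30 s are on the heart-failure-associated
#' periodic-breathing spectrum).
#'
#' @param envelope a [bed_series()] respiratory envelope (see
#'   [resp_envelope()]).
#' @param min_period_s minimum cycle length to flag.
#' @param min_duration_s minimum evaluable signal length (default 10 min).
#' @param max_lag_s autocorrelation horizon.
#' @return A list: `evaluable`, `flagged`, `period_s`, `acf_peak`.
#' @export
periodic_breathing <- function(envelope, min_period_s = 30,
                               min_duration_s = 600, max_lag_s = 180) {
  span <- diff(range(envelope$t))
  if (span < min_duration_s)
    return(list(evaluable = FALSE, flagged = FALSE, period_s = NA_real_,
                acf_peak = NA_real_))
  dec <- decimate_median(envelope$x, envelope$t, envelope$fs, out_fs = 2)
  v <- dec$x - mean(dec$x)
  fs2 <- 1 / median(diff(dec$t))
  a <- as.numeric(acf(v, lag.max = min(length(v) - 1, round(max_lag_s * fs2)),
                      plot = FALSE)$acf)
  pk <- find_peaks_prom(a, min_dist = round(5 * fs2), min_prom = 0.05)
  pk <- pk[pk > 1]
  if (!length(pk))
    return(list(evaluable = TRUE, flagged = FALSE, period_s = NA_real_,
                acf_peak = NA_real_))
  first <- pk[1]
  lag_s <- (first - 1) / fs2
  val <- a[first]
  list(evaluable = TRUE,
       flagged = (val >= 0.5 && lag_s > min_period_s),
       period_s = lag_s, acf_peak = val)
}
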