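#' Single-peak ballistocardiogram
#'
#' Converts each channel's raw BCG into an energy measure and composites the
#' channels into a series with one dominant peak per heartbeat: per-channel
#' bandpass 5-50 Hz (1-50 Hz in amplitude-analysis mode; the upper cutoff is
#' clipped below Nyquist at 80 Hz sampling), a 50 ms moving mean, a 150 ms
#' moving variance, channel summation, and a final 1-50 Hz bandpass. The
#' moving variance is quadratic in the underlying recoil amplitude, so peak
#' heights scale as the square of beat strength; [beat_magnitude()] returns
#' to amplitude scale.
#'
#' @param frame a [sensor_frame()].
#' @param cal optional [calibration_model()].
#' @param amplitude_mode lower the per-channel cutoff from 5 Hz to 1 Hz, used
#'   for beat-amplitude analytics.
#' @param mean_ms,var_ms smoothing window lengths in milliseconds.
#' @return A [bed_series()] single-peak BCG.
#' @export
single_peak_bcg <- function(frame, cal = NULL, amplitude_mode = FALSE,
                            mean_ms = 50, var_ms = 150) {
  if (!is.null(cal)) frame <- apply_calibration(frame, cal)
  fs <- frame_fs(frame)
  low <- if (amplitude_mode) 1 else 5
  acc <- 0
  for (j in seq_len(n_channels(frame))) {
    b <- suppressWarnings(bandpass(frame$channels[, j], low, 50, fs = fs))
    b <- moving_stat(b, mean_ms / 1000, "mean", fs = fs)
    b <- moving_stat(b, var_ms / 1000, "variance", fs = fs)
    acc <- acc + b
  }
  out <- suppressWarnings(bandpass(acc, 1, 50, fs = fs))
  bed_series(out, frame$timestamps, fs)
}

#' Beat detection on the single-peak BCG
#'
#' Peaks are searched inside steady regions (5 s minimum duration for the
#' cardiac scale), with minimum spacing 60/180 s (fastest plausible rate,
#' 180 beats/min) and prominence of at least 20% of the region's amplitude
#' scale.
#'
#' @param single_peak a [bed_series()] from [single_peak_bcg()].
#' @param steady data.frame of steady regions (5 s minimum); `NULL` treats
#'   the whole signal as steady.
#' @param min_spacing_s minimum inter-beat spacing in seconds.
#' @param prominence_frac prominence threshold fraction.
#' @return A `beat_series` data.frame: `time_s`, `amplitude` (single-peak-BCG
#'   peak height), `resp_phase` (filled by [respirophasic_coupling()],
#'   `"unknown"` here).
#' @export
find_beats <- function(single_peak, steady = NULL, min_spacing_s = 60 / 180,
                       prominence_frac = 0.20) {
  x <- single_peak$x; t <- single_peak$t; fs <- single_peak$fs
  regions <- if (is.null(steady))
    data.frame(start_s = t[1], end_s = t[length(t)]) else steady
  tm <- numeric(0); amp <- numeric(0)
  for (i in seq_len(nrow(regions))) {
    sel <- which(t >= regions$start_s[i] & t <= regions$end_s[i])
    if (length(sel) < 5) next
    xr <- x[sel]
    d <- diff(xr)
    cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
    cand <- cand[xr[cand] > 0] # beats are positive energy humps
    if (!length(cand)) next
    prom <- peak_prominence_cpp(xr, cand)
    # the single-peak BCG is a sparse pulse train, so sample quantiles of
    # the signal underestimate the beat scale. At least duration/1.5 s true
    # beats exist (rates are >= 40 bpm), so the (k/2)-th largest candidate
    # prominence is a real beat's; gate at 20% of that
    k <- ceiling((t[sel[length(sel)]] - t[sel[1]]) / 1.5)
    ps <- sort(prom, decreasing = TRUE)
    scale <- ps[min(max(1L, ceiling(k / 2)), length(ps))]
    if (scale <= 0) next
    cand <- cand[prom >= prominence_frac * scale]
    if (!length(cand)) next
    # the beat train repeats at the inter-beat interval, so the dominant
    # autocorrelation lag estimates it; half that period as the spacing
    # floor suppresses filter rebound lobes between beats (prominent at low
    # rates, where the beat fundamental falls below the 1 Hz cutoff)
    spacing <- min_spacing_s
    lag_max <- min(length(xr) - 1L, as.integer(1.6 * fs))
    if (lag_max > as.integer(0.9 * min_spacing_s * fs)) {
      a <- as.numeric(acf(xr, lag.max = lag_max, plot = FALSE,
                          demean = TRUE)$acf)
      lo <- as.integer(min_spacing_s * fs)
      pk_a <- find_peaks_prom(a, min_dist = lo, min_prom = 0.05)
      pk_a <- pk_a[pk_a > lo]
      if (length(pk_a)) {
        vals <- a[pk_a]
        strong <- pk_a[vals >= 0.9 * max(vals)]
        best <- strong[1] # fundamental, not a multiple of it
        spacing <- max(min_spacing_s, 0.5 * (best - 1) / fs)
      }
    }
    ord <- cand[order(xr[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (p in ord)
      if (!length(kept) || all(abs(kept - p) >= spacing * fs))
        kept <- c(kept, p)
    kept <- sort(kept)
    # sub-sample vertex refinement of time and height (parabolic)
    for (p in kept) {
      if (p > 1 && p < length(xr)) {
        den <- xr[p - 1] - 2 * xr[p] + xr[p + 1]
        dlt <- if (den < 0) 0.5 * (xr[p - 1] - xr[p + 1]) / den else 0
        dlt <- max(-0.5, min(0.5, dlt))
        tm <- c(tm, t[sel[p]] + dlt / fs)
        amp <- c(amp, xr[p] - 0.25 * (xr[p - 1] - xr[p + 1]) * dlt)
      } else {
        tm <- c(tm, t[sel[p]])
        amp <- c(amp, xr[p])
      }
    }
  }
  o <- order(tm)
  structure(data.frame(time_s = tm[o], amplitude = amp[o],
                       resp_phase = rep("unknown", length(tm))),
            class = c("beat_series", "data.frame"))
}

#' Beat magnitude on amplitude scale
#'
#' The single-peak BCG is an energy (variance) measure; its peak heights are
#' quadratic in the recoil amplitude. This returns `sqrt(amplitude)`, the
#' measure used by the coupling and post-ectopy analytics so that amplitude
#' ratios are recovered on their natural scale.
#'
#' @param beats a `beat_series` from [find_beats()].
#' @return Numeric vector of beat magnitudes.
#' @export
beat_magnitude <- function(beats) sqrt(pmax(beats$amplitude, 0))

#' Heart-rate epochs
#'
#' Identical contract to [respiratory_rate()] but on cardiac beats: every
#' 30 s, rate = 60 / median inter-beat interval in the centered 5-min window;
#' epochs with more than 45 s of unsteady physiology are invalid.
#'
#' @param beats a `beat_series` from [find_beats()].
#' @inheritParams respiratory_rate
#' @return A data.frame of rate epochs.
#' @export
heart_rate <- function(beats, duration_s, epoch_s = 30, window_s = 300,
                       steady = NULL, max_unsteady_s = 45) {
  rate_epochs(beats$time_s, duration_s, epoch_s, window_s, steady,
              max_unsteady_s)
}

#' Respirophasic beat-amplitude coupling
#'
#' Labels each beat inspiration/expiration by the respiratory phase at beat
#' onset (inspiration = the rising limb of the respiratory composite) and
#' compares beat magnitudes between phases: changes in intrathoracic pressure
#' modulate venous return and stroke volume, so inspiratory recoil amplitudes
#' exceed expiratory ones when coupling is present. Significance via the
#' two-sided Mann-Whitney test.
#'
#' @param beats a `beat_series`.
#' @param composite the respiratory composite ([bed_series()]) on the same
#'   time base.
#' @param slope_smooth_s smoothing applied to the composite derivative used
#'   for the phase rule.
#' @param onset_lag_s lag of the single-peak energy maximum behind the
#'   mechanical beat onset, subtracted before reading the phase.
#' @param min_per_phase minimum beats per phase for evaluation.
#' @return A list: `inspiration`, `expiration` (magnitude vectors),
#'   `ratio` (inspiratory mean / expiratory mean), `p_value`, `evaluable`,
#'   `beats` (with `resp_phase` filled).
#' @export
respirophasic_coupling <- function(beats, composite, slope_smooth_s = 0.5,
                                   min_per_phase = 10, onset_lag_s = 0.1) {
  stopifnot(inherits(composite, "bed_series"))
  fs <- composite$fs
  slope <- c(0, diff(moving_stat(composite$x, slope_smooth_s, "mean",
                                 fs = fs)))
  # the brisk inspiratory upstroke has a distinctly positive slope; the long
  # expiratory decay flattens toward zero. Gate inspiration on a fraction of
  # the strong-upstroke slope; weakly-rising samples (upstroke corners) are
  # ambiguous and labelled unknown rather than forced into either phase
  S <- quantile(pmax(slope, 0), 0.98, names = FALSE)
  # the single-peak energy maximum lags the mechanical beat onset by about
  # the recoil complex's rise time; read the phase at onset
  idx <- vapply(beats$time_s - onset_lag_s,
                function(x) which.min(abs(composite$t - x)), integer(1))
  phase <- ifelse(slope[idx] > 0.15 * S, "inspiration",
                  ifelse(slope[idx] < 0.05 * S, "expiration", "unknown"))
  beats$resp_phase <- phase
  mag <- beat_magnitude(beats)
  insp <- mag[phase == "inspiration"]
  expn <- mag[phase == "expiration"]
  if (length(insp) < min_per_phase || length(expn) < min_per_phase)
    return(list(inspiration = insp, expiration = expn, ratio = NA_real_,
                p_value = NA_real_, evaluable = FALSE, beats = beats))
  list(inspiration = insp, expiration = expn,
       ratio = mean(insp) / mean(expn),
       p_value = wilcox.test(insp, expn)$p.value,
       evaluable = TRUE, beats = beats)
}

#' Post-ectopy beat-amplitude ratio
#'
#' Premature beats are mechanically weak (short diastolic filling) and the
#' first post-ectopic beat is augmented (prolonged filling). For each ectopic
#' run, the ratio of the first post-ectopy beat magnitude to the mean
#' magnitude of the 3 beats preceding the run quantifies that augmentation.
#' Events with fewer than 3 preceding beats are skipped.
#'
#' @param beats a `beat_series`.
#' @param ectopy_intervals data.frame with `start_s`, `end_s` (from truth,
#'   annotation, or [detect_ectopy()]).
#' @param n_pre number of preceding beats to average.
#' @return A list: `ratios` (per event), `mean_ratio`, `sd_ratio`,
#'   `n_events`, `n_skipped`.
#' @export
ectopy_amplitude_ratio <- function(beats, ectopy_intervals, n_pre = 3) {
  mag <- beat_magnitude(beats)
  ratios <- numeric(0)
  skipped <- 0L
  for (i in seq_len(nrow(ectopy_intervals))) {
    a <- ectopy_intervals$start_s[i]; b <- ectopy_intervals$end_s[i]
    pre <- which(beats$time_s < a)
    if (length(pre) < n_pre) {
      skipped <- skipped + 1L
      next
    }
    pre3 <- tail(pre, n_pre)
    # the post-ectopic beat follows the compensatory pause; take the
    # largest beat in that window so residual lobes of the ectopic run
    # are not mistaken for it
    ibi <- median(diff(beats$time_s[pre3]))
    if (!is.finite(ibi) || ibi <= 0) ibi <- 1
    post <- which(beats$time_s > b & beats$time_s <= b + 2 * ibi)
    if (!length(post)) {
      skipped <- skipped + 1L
      next
    }
    post1 <- post[which.max(mag[post])]
    ratios <- c(ratios, mag[post1] / mean(mag[pre3]))
  }
  list(ratios = ratios,
       mean_ratio = if (length(ratios)) mean(ratios) else NA_real_,
       sd_ratio = if (length(ratios) > 1) sd(ratios) else NA_real_,
       n_events = length(ratios), n_skipped = skipped)
}

#' Heuristic ectopy localisation from inter-beat intervals
#'
#' Flags a candidate ectopic run where an inter-beat interval falls below 70%
#' of the local median and the following interval exceeds 120% (premature
#' beat plus compensatory pause). Intended only to feed
#' [ectopy_amplitude_ratio()] when no annotation is available, not for
#' diagnosis.
#'
#' @param beats a `beat_series`.
#' @param short_frac,long_frac interval thresholds relative to the local
#'   median.
#' @param local_n window (in beats) for the local median interval.
#' @return A data.frame `start_s`, `end_s` of candidate ectopic runs.
#' @export
detect_ectopy <- function(beats, short_frac = 0.7, long_frac = 1.2,
                          local_n = 21) {
  tb <- beats$time_s
  out <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (length(tb) < 5) return(out)
  iv <- diff(tb)
  half <- local_n %/% 2
  for (i in seq_len(length(iv) - 1)) {
    lo <- max(1, i - half); hi <- min(length(iv), i + half)
    loc <- median(iv[lo:hi])
    if (iv[i] < short_frac * loc && iv[i + 1] > long_frac * loc) {
      out <- rbind(out, data.frame(start_s = tb[i] + 0.25 * iv[i],
                                   end_s = tb[i + 1] + 0.25 * loc))
    }
  }
  out
}
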