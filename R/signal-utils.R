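#' Zero-phase Butterworth bandpass filter
#'
#' Applies a Butterworth bandpass forward and backward (`signal::filtfilt`),
#' so the filter is zero-phase and peak timing is not shifted. The DC
#' component is removed by construction. When `high_hz` meets or exceeds the
#' Nyquist frequency it is clipped to 0.99 x Nyquist with a warning (the
#' canonical 50 Hz upper cardiac cutoff exceeds Nyquist at 80 Hz sampling).
#'
#' @param x numeric vector or `bed_series`.
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz`.
#' @param fs sampling rate in Hz (ignored when `x` is a `bed_series`).
#' @param order overall filter order (default 4, i.e. a 2nd-order section per
#'   band edge); must be even.
#' @return Filtered signal, same type and length as the input.
#' @export
bandpass <- function(x, low_hz, high_hz, fs = NULL, order = 4) {
  if (inherits(x, "bed_series")) {
    out <- x
    out$x <- bandpass(x$x, low_hz, high_hz, fs = x$fs, order = order)
    return(out)
  }
  if (is.null(fs)) stop("`fs` must be supplied for plain numeric input")
  if (!(low_hz > 0) || !(high_hz > low_hz))
    stop("band edges must satisfy 0 < low_hz < high_hz")
  if (order %% 2 != 0 || order < 2) stop("`order` must be a positive even number")
  nyq <- fs / 2
  if (high_hz >= nyq) {
    warning(sprintf("high cutoff %.3g Hz >= Nyquist (%.3g Hz); clipped to %.3g Hz",
                    high_hz, nyq, 0.99 * nyq))
    high_hz <- 0.99 * nyq
  }
  if (low_hz >= high_hz) stop("low cutoff at or above (clipped) high cutoff")
  filt <- signal::butter(order / 2, c(low_hz, high_hz) / nyq, type = "pass")
  as.numeric(signal::filtfilt(filt, x - mean(x)))
}

#' Centered moving statistic
#'
#' Moving mean or moving variance over a centered window. Windows shrink at
#' the signal edges so the output has the same length as the input. The
#' variance uses the unbiased (n - 1) denominator, matching [stats::var()].
#'
#' @param x numeric vector or `bed_series`.
#' @param window_s window length in seconds.
#' @param stat `"mean"` or `"variance"`.
#' @param fs sampling rate in Hz (ignored for `bed_series` input).
#' @return Same type and length as the input.
#' @export
moving_stat <- function(x, window_s, stat = c("mean", "variance"), fs = NULL) {
  stat <- match.arg(stat)
  if (inherits(x, "bed_series")) {
    out <- x
    out$x <- moving_stat(x$x, window_s, stat, fs = x$fs)
    return(out)
  }
  if (is.null(fs)) stop("`fs` must be supplied for plain numeric input")
  n <- length(x)
  w <- max(3L, as.integer(round(window_s * fs)))
  if (window_s <= 2 / fs) stop("`window_s` must exceed 2 sample intervals")
  if (w > n) stop("window longer than signal")
  half <- w %/% 2L
  idx <- seq_len(n)
  lo <- pmax(1L, idx - half)
  hi <- pmin(n, idx + half)
  cnt <- hi - lo + 1L
  mu0 <- mean(x)
  xc <- x - mu0 # center to limit cancellation in the variance sums
  S1 <- c(0, cumsum(xc))
  m <- (S1[hi + 1L] - S1[lo]) / cnt
  if (stat == "mean") return(m + mu0)
  S2 <- c(0, cumsum(xc * xc))
  ss <- (S2[hi + 1L] - S2[lo]) - cnt * m * m
  v <- ss / pmax(cnt - 1L, 1L)
  pmax(v, 0)
}

moving_rms <- function(x, window_s, fs) {
  sqrt(pmax(moving_stat(x^2, window_s, "mean", fs = fs), 0))
}

# centered moving maximum with shrunken edge windows
moving_max <- function(x, window_s, fs) {
  h <- max(1L, as.integer(round(window_s * fs / 2)))
  moving_max_cpp(x, h)
}

#' Detect steady (movement-free) regions from a moving-variance series
#'
#' Maximal runs where the variance stays at or below `threshold`, keeping
#' only runs at least `min_duration_s` long (the canonical minima are 10 s
#' for respiratory analysis and 5 s for ballistocardiography). Regions are
#' disjoint and time-ordered.
#'
#' @param variance a `bed_series` of moving variance (or numeric vector with
#'   `t` supplied).
#' @param threshold variance threshold (signal units squared); if `NULL`,
#'   an adaptive default of 4 x the 10th percentile of the series is used.
#' @param min_duration_s minimum region duration in seconds.
#' @param t timestamps for plain numeric input.
#' @return A data.frame with columns `start_s`, `end_s`, `mean_variance`.
#' @export
steady_regions <- function(variance, threshold = NULL, min_duration_s = 10, t = NULL) {
  if (inherits(variance, "bed_series")) {
    t <- variance$t
    v <- variance$x
  } else {
    v <- variance
    if (is.null(t)) stop("timestamps `t` required for plain numeric input")
  }
  if (is.null(threshold)) threshold <- steady_threshold(v)
  if (threshold <= 0) stop("`threshold` must be positive")
  quiet <- v <= threshold
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    mean_variance = numeric(0))
  for (k in keep) {
    i0 <- starts[k]; i1 <- ends[k]
    dur <- t[i1] - t[i0]
    if (dur >= min_duration_s) {
      out <- rbind(out, data.frame(start_s = t[i0], end_s = t[i1],
                                   mean_variance = mean(v[i0:i1])))
    }
  }
  rownames(out) <- NULL
  out
}

#' Adaptive steady-region variance threshold
#'
#' Default threshold for [steady_regions()]: 4 x the 10th percentile of the
#' moving-variance series, an adaptive level that tracks the night's
#' quiescent floor.
#'
#' @param v numeric vector or `bed_series` of moving variance.
#' @return A scalar threshold.
#' @export
steady_threshold <- function(v) {
  if (inherits(v, "bed_series")) v <- v$x
  thr <- 4 * as.numeric(quantile(v, 0.10, names = FALSE))
  if (thr <= 0) thr <- .Machine$double.eps
  thr
}

# Local maxima with prominence and minimum-spacing constraints.
# Returns integer sample indices, time-ordered.
find_peaks_prom <- function(x, min_dist, min_prom) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (!length(cand)) return(integer(0))
  prom <- peak_prominence_cpp(x, cand)
  cand <- cand[prom >= min_prom]
  if (!length(cand)) return(integer(0))
  # enforce spacing greedily by height
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= min_dist)) kept <- c(kept, p)
  }
  sort(kept)
}

# restrict a logical mask of samples to given [start_s, end_s] regions
region_mask <- function(t, regions) {
  m <- rep(FALSE, length(t))
  if (is.null(regions) || nrow(regions) == 0) return(m)
  for (i in seq_len(nrow(regions)))
    m[t >= regions$start_s[i] & t <= regions$end_s[i]] <- TRUE
  m
}
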