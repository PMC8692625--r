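#' Sampled series
#'
#' A lightweight container for a uniformly sampled scalar signal: values `x`,
#' timestamps `t` (seconds since session start) and sampling rate `fs` (Hz).
#' Most pipeline stages consume and return `bed_series` objects.
#'
#' @param x numeric vector of samples.
#' @param t numeric vector of timestamps (seconds), same length as `x`.
#' @param fs sampling rate in Hz.
#' @return An object of class `bed_series`.
#' @export
bed_series <- function(x, t, fs) {
  stopifnot(is.numeric(x), is.numeric(t), length(x) == length(t), fs > 0)
  structure(list(t = as.numeric(t), x = as.numeric(x), fs = fs),
            class = "bed_series")
}

#' @export
print.bed_series <- function(x, ...) {
  cat(sprintf("<bed_series> %d samples @ %.3g Hz, %.1f s span, range [%.4g, %.4g]\n",
              length(x$x), x$fs, diff(range(x$t)), min(x$x), max(x$x)))
  invisible(x)
}

#' @export
length.bed_series <- function(x) length(x$x)

#' @export
plot.bed_series <- function(x, ..., xlab = "time (s)", ylab = "value") {
  plot(x$t, x$x, type = "l", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

as_series <- function(x, t, fs) bed_series(x, t, fs)
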