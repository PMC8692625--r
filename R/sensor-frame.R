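#' Multi-channel force recording
#'
#' The universal input to the pipeline: a timestamped multi-channel force
#' recording from the load sensors beneath the bed legs. Timestamps are
#' seconds since session start and must be strictly increasing; the canonical
#' configuration is 4 channels sampled at ~80 Hz.
#'
#' @param timestamps numeric vector, seconds since session start, strictly
#'   increasing.
#' @param channels numeric matrix, one column per sensor, `nrow ==
#'   length(timestamps)`.
#' @param units `"raw_AU"` (digitizer units) or `"lbs"` (calibrated).
#' @param nominal_rate nominal sampling rate in Hz; must lie in \[60, 100\]
#'   and agree with the median inter-sample interval within 20%.
#' @return An object of class `sensor_frame`.
#' @export
sensor_frame <- function(timestamps, channels, units = c("raw_AU", "lbs"),
                         nominal_rate = 80) {
  units <- match.arg(units)
  channels <- as.matrix(channels)
  timestamps <- as.numeric(timestamps)
  if (!is.numeric(channels)) stop("`channels` must be numeric")
  if (nrow(channels) != length(timestamps))
    stop("`channels` must have one row per timestamp")
  if (ncol(channels) < 1) stop("at least one channel is required")
  dt <- diff(timestamps)
  bad <- which(dt <= 0)
  if (length(bad))
    stop(sprintf("timestamps not strictly increasing: first violation at index %d",
                 bad[1] + 1L))
  if (nominal_rate < 60 || nominal_rate > 100)
    stop("`nominal_rate` must lie in [60, 100] Hz")
  if (length(dt)) {
    med_dt <- median(dt)
    if (abs(med_dt - 1 / nominal_rate) > 0.2 / nominal_rate)
      stop(sprintf("median sample interval %.4g s inconsistent with nominal rate %g Hz",
                   med_dt, nominal_rate))
  }
  structure(list(timestamps = timestamps, channels = unname(channels),
                 units = units, nominal_rate = nominal_rate),
            class = "sensor_frame")
}

#' @export
print.sensor_frame <- function(x, ...) {
  cat(sprintf("<sensor_frame> %d samples x %d channels, %.1f s @ %g Hz nominal, units: %s\n",
              nrow(x$channels), ncol(x$channels),
              diff(range(x$timestamps)), x$nominal_rate, x$units))
  invisible(x)
}

#' @export
summary.sensor_frame <- function(object, ...) {
  s <- apply(object$channels, 2, function(c) c(mean = mean(c), sd = sd(c)))
  cat(sprintf("sensor_frame: %d samples, %d channels, %.1f s, units %s\n",
              nrow(object$channels), ncol(object$channels),
              diff(range(object$timestamps)), object$units))
  print(round(t(s), 4))
  invisible(s)
}

n_channels <- function(frame) ncol(frame$channels)

frame_fs <- function(frame) frame$nominal_rate

#' Read a sensor recording
#'
#' Reads the columnar CSV dialect `t,ch0,ch1,...` (time in seconds or
#' ISO-8601; UTF-8, comma separated). Non-monotonic timestamps are rejected,
#' not silently sorted. HDF5 input is not supported by this build and raises
#' an error.
#'
#' @param path file path.
#' @param format `"csv"` or `"hdf5"`.
#' @param nominal_rate nominal sampling rate; if `NULL`, inferred from the
#'   median inter-sample interval.
#' @param units declared units of the channels.
#' @return A [sensor_frame()].
#' @export
read_frame <- function(path, format = c("csv", "hdf5"),
                       nominal_rate = NULL, units = "raw_AU") {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("HDF5 input is not supported by this build; use the CSV dialect")
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (!ncol(raw) >= 2) stop("format error: need a time column and >=1 channel")
  if (!("t" %in% names(raw)))
    stop("format error: missing time column `t`")
  tcol <- raw[["t"]]
  tnum <- suppressWarnings(as.numeric(tcol))
  if (anyNA(tnum)) {
    # ISO-8601 fallback: convert to seconds since the first sample
    tp <- as.POSIXct(tcol, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
    if (anyNA(tp))
      stop(sprintf("parse error: non-numeric time at row %d",
                   which(is.na(tnum))[1]))
    tnum <- as.numeric(tp) - as.numeric(tp[1])
  }
  chn <- setdiff(names(raw), "t")
  ch <- matrix(NA_real_, nrow(raw), length(chn))
  for (j in seq_along(chn)) {
    v <- suppressWarnings(as.numeric(raw[[chn[j]]]))
    if (anyNA(v))
      stop(sprintf("parse error: non-numeric value in column `%s` at row %d",
                   chn[j], which(is.na(v))[1]))
    ch[, j] <- v
  }
  if (is.null(nominal_rate)) {
    nominal_rate <- 1 / median(diff(tnum))
    nominal_rate <- min(max(nominal_rate, 60), 100)
  }
  sensor_frame(tnum, ch, units = units, nominal_rate = nominal_rate)
}

#' Write a sensor recording
#'
#' Writes the CSV dialect read by [read_frame()] with full double precision,
#' so a write/read round trip reproduces the frame bit for bit.
#'
#' @param frame a [sensor_frame()].
#' @param path output file path.
#' @param format only `"csv"` is supported.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("HDF5 output is not supported by this build; use the CSV dialect")
  stopifnot(inherits(frame, "sensor_frame"))
  cols <- c(list(sprintf("%.17g", frame$timestamps)),
            lapply(seq_len(ncol(frame$channels)),
                   function(j) sprintf("%.17g", frame$channels[, j])))
  hdr <- c("t", paste0("ch", seq_len(ncol(frame$channels)) - 1L))
  lines <- c(paste(hdr, collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}
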