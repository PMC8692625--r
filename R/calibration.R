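#' Calibration model for a set of bed sensors
#'
#' Holds one multiplicative gain per channel (relative sensitivities, the
#' first channel acting as the gauge reference) and an affine map from
#' digitizer units (AU) to pounds: `lbs = (sum_j gain_j * AU_j - offset) * scale`.
#'
#' @param channel_gains positive numeric vector of per-channel gains, or
#'   `NULL` for identity gains.
#' @param affine_offset AU reading of the unloaded system (applies to the
#'   gain-weighted channel sum).
#' @param affine_scale pounds per AU; must be positive.
#' @return An object of class `bed_calibration`.
#' @export
calibration_model <- function(channel_gains = NULL, affine_offset = 0,
                              affine_scale = 1) {
  if (!is.null(channel_gains)) {
    if (any(!is.finite(channel_gains)) || any(channel_gains <= 0))
      stop("all channel gains must be positive and finite")
  }
  if (!is.finite(affine_scale) || affine_scale <= 0)
    stop("`affine_scale` must be positive")
  structure(list(channel_gains = channel_gains,
                 affine_offset = affine_offset,
                 affine_scale = affine_scale),
            class = "bed_calibration")
}

#' @export
print.bed_calibration <- function(x, ...) {
  g <- if (is.null(x$channel_gains)) "identity" else
    paste(sprintf("%.4f", x$channel_gains), collapse = ", ")
  cat(sprintf("<bed_calibration> gains: %s; lbs = (AU - %.6g) * %.6g\n",
              g, x$affine_offset, x$affine_scale))
  invisible(x)
}

cal_gains <- function(cal, nch) {
  if (is.null(cal$channel_gains)) rep(1, nch) else {
    if (length(cal$channel_gains) != nch)
      stop("configuration error: calibration has a different channel count than the frame")
    cal$channel_gains
  }
}

#' Joint calibration of channel gains from repeated placements of one load
#'
#' The same load is recorded at several bed positions; per-channel gains are
#' fitted to minimise, in the least-squares sense, the variance of the
#' gain-weighted channel sum across placements. The first channel is the
#' gauge reference (gain fixed at 1), since a common rescaling of all gains
#' is unidentifiable.
#'
#' @param frames list of [sensor_frame()]s (>= 2), each a recording of the
#'   SAME load at a different position; each frame is summarised by its
#'   per-channel mean reading.
#' @param known_load optional true load in lbs; when supplied, the affine
#'   scale is set so the mean fitted total equals `known_load` (assumes
#'   tare-subtracted readings).
#' @return A [calibration_model()].
#' @export
fit_joint_calibration <- function(frames, known_load = NULL) {
  if (!is.list(frames) || length(frames) < 2)
    stop("insufficient data: need at least 2 placements of the same load")
  M <- t(vapply(frames, function(f) colMeans(f$channels),
                numeric(ncol(frames[[1]]$channels))))
  P <- nrow(M); C <- ncol(M)
  Mc <- scale(M, center = TRUE, scale = FALSE)
  degen <- apply(Mc, 2, function(col) max(abs(col)) < 1e-9 * max(1, max(abs(M))))
  if (any(degen))
    stop(sprintf("degenerate design: channel(s) %s constant across placements",
                 paste(which(degen), collapse = ", ")))
  if (C == 1) return(calibration_model(1))
  # minimise Var(m_1 + sum_{j>1} g_j m_j) over g: centered least squares
  X <- Mc[, -1, drop = FALSE]
  y <- Mc[, 1]
  g_rest <- tryCatch(
    as.numeric(solve(crossprod(X), -crossprod(X, y))),
    error = function(e) stop("degenerate design: placement matrix is rank deficient"))
  gains <- c(1, g_rest)
  if (any(gains <= 0))
    stop("degenerate design: fitted gains not all positive; placements do not span the bed")
  scale_lbs <- 1
  if (!is.null(known_load)) {
    tot <- as.numeric(M %*% gains)
    scale_lbs <- known_load / mean(tot)
  }
  calibration_model(gains, affine_offset = 0, affine_scale = scale_lbs)
}

#' Two-point affine calibration (AU to lbs)
#'
#' Fixes the affine units map from two readings of the gain-weighted channel
#' sum: the unloaded reading maps to 0 lbs and the reference-load reading to
#' `ref_load` lbs, exactly.
#'
#' @param reading_zero AU reading with the bed empty.
#' @param reading_ref AU reading with the reference load applied.
#' @param ref_load reference load in lbs (> 0).
#' @param cal optional existing [calibration_model()] whose channel gains are
#'   kept; its affine part is replaced.
#' @return A [calibration_model()].
#' @export
two_point_calibrate <- function(reading_zero, reading_ref, ref_load, cal = NULL) {
  if (!is.finite(ref_load) || ref_load <= 0) stop("`ref_load` must be positive")
  if (reading_ref == reading_zero)
    stop("reference and zero readings are equal; affine scale undefined")
  scale <- ref_load / (reading_ref - reading_zero)
  if (scale <= 0) stop("reference reading below zero reading; check inputs")
  calibration_model(if (is.null(cal)) NULL else cal$channel_gains,
                    affine_offset = reading_zero, affine_scale = scale)
}

#' Convert an AU reading of the gain-weighted sum to pounds
#'
#' @param cal a [calibration_model()].
#' @param reading_au AU value(s) of the gain-weighted channel sum.
#' @return Value(s) in lbs.
#' @export
au_to_lbs <- function(cal, reading_au) {
  (reading_au - cal$affine_offset) * cal$affine_scale
}

#' Apply a calibration to a frame
#'
#' Returns a frame in pounds: each channel is scaled by its gain and the
#' affine scale; the affine offset (empty-system baseline of the summed
#' reading) is split equally across channels so the channel sum matches
#' [total_weight()] exactly.
#'
#' @param frame a [sensor_frame()].
#' @param cal a [calibration_model()].
#' @return A calibrated [sensor_frame()] with `units = "lbs"`.
#' @export
apply_calibration <- function(frame, cal) {
  g <- cal_gains(cal, n_channels(frame))
  ch <- sweep(frame$channels, 2, g, `*`)
  ch <- (ch - cal$affine_offset / ncol(ch)) * cal$affine_scale
  sensor_frame(frame$timestamps, ch, units = "lbs",
               nominal_rate = frame$nominal_rate)
}
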