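#' Physiologic plausibility filter for rate epochs
#'
#' Keeps only epochs with a physiologically reasonable rate, strictly inside
#' the bounds: 6 < bpm < 40 for respiratory rate, 60 < bpm < 120 for heart
#' rate (boundary values are excluded). Invalid epochs (no rate) are dropped
#' too. The filter is idempotent.
#'
#' @param epochs a data.frame of rate epochs (from [respiratory_rate()] or
#'   [heart_rate()]).
#' @param kind `"rr"` or `"hr"`.
#' @return The filtered epochs, with counts in attributes `n_filtered`
#'   (plausibility-rejected) and `n_invalid`.
#' @export
plausibility_filter <- function(epochs, kind = c("rr", "hr")) {
  kind <- match.arg(kind)
  b <- if (kind == "rr") c(6, 40) else c(60, 120)
  ok_valid <- epochs$valid & !is.na(epochs$rate_bpm)
  ok_range <- ok_valid & epochs$rate_bpm > b[1] & epochs$rate_bpm < b[2]
  out <- epochs[ok_range, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_filtered") <- sum(ok_valid & !ok_range)
  attr(out, "n_invalid") <- sum(!ok_valid)
  out
}

#' Daily summaries of rates, weight and time-in-bed
#'
#' Aggregates 30 s epochs into noon-to-noon days: mean and sd of the
#' plausibility-filtered respiratory and heart rates, percent time-in-bed,
#' and the daily weight. Days with no valid epochs report `NA`, never zero.
#'
#' @param rr_epochs,hr_epochs rate epochs (unfiltered; the plausibility
#'   filter is applied here).
#' @param occupancy result of [occupancy()] (for %TIB), or `NULL`.
#' @param weights optional data.frame from [daily_weight()].
#' @param session_start wall-clock session start (`POSIXct` or epoch
#'   seconds).
#' @return A data.frame, one row per day: `date`, `mean_rr_bpm`, `sd_rr_bpm`,
#'   `n_valid_rr_epochs`, `mean_hr_bpm`, `sd_hr_bpm`, `n_valid_hr_epochs`,
#'   `pct_time_in_bed`, `weight_lbs`.
#' @export
daily_summary <- function(rr_epochs = NULL, hr_epochs = NULL,
                          occupancy = NULL, weights = NULL,
                          session_start = 0) {
  t0 <- as.numeric(session_start)
  day_of <- function(tt) floor((t0 + tt - 43200) / 86400)
  days <- integer(0)
  if (!is.null(rr_epochs)) days <- c(days, day_of(rr_epochs$epoch_start_s))
  if (!is.null(hr_epochs)) days <- c(days, day_of(hr_epochs$epoch_start_s))
  if (!is.null(occupancy)) days <- c(days, day_of(occupancy$epochs$epoch_start_s))
  if (!length(days)) return(data.frame())
  days <- sort(unique(days))
  rrf <- if (!is.null(rr_epochs)) plausibility_filter(rr_epochs, "rr")
  hrf <- if (!is.null(hr_epochs)) plausibility_filter(hr_epochs, "hr")
  rows <- lapply(days, function(d) {
    pick <- function(ep) ep[day_of(ep$epoch_start_s) == d, , drop = FALSE]
    stats_of <- function(ep) {
      if (is.null(ep) || !nrow(ep)) return(c(NA_real_, NA_real_, 0))
      c(mean(ep$rate_bpm),
        if (nrow(ep) > 1) sd(ep$rate_bpm) else 0, nrow(ep))
    }
    rr <- stats_of(if (is.null(rrf)) NULL else pick(rrf))
    hr <- stats_of(if (is.null(hrf)) NULL else pick(hrf))
    tib <- NA_real_
    if (!is.null(occupancy)) {
      oc <- pick(occupancy$epochs)
      if (nrow(oc)) tib <- 100 * mean(oc$in_bed)
    }
    w <- NA_real_
    if (!is.null(weights)) {
      dd <- as.Date(d + 1, origin = "1970-01-01")
      wi <- weights$weight_lbs[weights$date == dd]
      if (length(wi)) w <- wi[1]
    }
    data.frame(date = as.Date(d + 1, origin = "1970-01-01"),
               mean_rr_bpm = rr[1], sd_rr_bpm = rr[2],
               n_valid_rr_epochs = as.integer(rr[3]),
               mean_hr_bpm = hr[1], sd_hr_bpm = hr[2],
               n_valid_hr_epochs = as.integer(hr[3]),
               pct_time_in_bed = tib, weight_lbs = w)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Time-of-day x day heatmap matrix of rate epochs
#'
#' Reshapes 30 s epochs into a matrix with 2880 rows (30 s slots across the
#' noon-to-noon 24 h) and one column per day; cells below `value_floor` are
#' emitted as missing (the display-floor convention: 10 bpm for respiratory
#' rate, 60 bpm for heart rate).
#'
#' @param epochs a data.frame of rate epochs (typically plausibility
#'   filtered).
#' @param value_floor cells strictly below this value become `NA`; `NULL`
#'   disables the floor.
#' @param session_start wall-clock session start (`POSIXct` or epoch
#'   seconds).
#' @param epoch_s epoch length in seconds.
#' @return A numeric matrix (2880 x n_days) with ISO dates as column names;
#'   row `i` is the slot starting `(i-1) * epoch_s` seconds after noon.
#' @export
heatmap_export <- function(epochs, value_floor = NULL, session_start = 0,
                           epoch_s = 30) {
  t0 <- as.numeric(session_start)
  slots_per_day <- as.integer(86400 / epoch_s)
  abs_t <- t0 + epochs$epoch_start_s - 43200 # seconds since a noon boundary
  day <- floor(abs_t / 86400)
  slot <- as.integer(floor((abs_t - day * 86400) / epoch_s)) + 1L
  day0 <- floor((t0 - 43200) / 86400) # the session's first day
  days <- seq(min(c(day0, day)), max(day))
  M <- matrix(NA_real_, slots_per_day, length(days))
  colnames(M) <- as.character(as.Date(days + 1, origin = "1970-01-01"))
  v <- epochs$rate_bpm
  if (!is.null(value_floor)) v[v < value_floor] <- NA_real_
  M[cbind(slot, match(day, days))] <- v
  M
}

#' Write a heatmap matrix as CSV
#'
#' First column is the time-of-day slot (seconds after noon), subsequent
#' columns are ISO dates; missing cells are empty.
#'
#' @param M a matrix from [heatmap_export()].
#' @param path output path.
#' @param epoch_s epoch length in seconds.
#' @return `path`, invisibly.
#' @export
write_heatmap_csv <- function(M, path, epoch_s = 30) {
  df <- data.frame(slot_s = (seq_len(nrow(M)) - 1L) * epoch_s, M,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
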