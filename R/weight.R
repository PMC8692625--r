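#' Continuous total weight from a calibrated frame
#'
#' Pointwise gain-weighted sum of all channels mapped through the affine
#' AU-to-lbs model: summing the loads under the four legs makes the total
#' invariant to where on the bed the load rests.
#'
#' @param frame a [sensor_frame()].
#' @param cal a [calibration_model()]; identity by default (for frames
#'   already in lbs).
#' @return A [bed_series()] of total load in lbs.
#' @export
total_weight <- function(frame, cal = calibration_model()) {
  g <- cal_gains(cal, n_channels(frame))
  tot <- au_to_lbs(cal, as.numeric(frame$channels %*% g))
  bed_series(tot, frame$timestamps, frame_fs(frame))
}

#' Detect step changes in the total-weight series
#'
#' Extracts the large differential weight changes (bed entries/exits, objects
#' added or removed): candidate transitions are found where a short-scale
#' median differential exceeds `min_step_lbs`, and each event's delta is the
#' difference of the medians of the flanking plateaus (`settle_s` long,
#' excluding a guard band of transition samples). Sloped pseudo-plateaus are
#' rejected, so a continuous ramp yields no events.
#'
#' @param total a [bed_series()] from [total_weight()].
#' @param min_step_lbs minimum step magnitude (default 5 lbs for person
#'   events; use ~0.02 lbs for high-sensitivity aliquot work).
#' @param settle_s plateau window length in seconds.
#' @param guard_s transition samples within `guard_s` of the candidate time
#'   are excluded from both plateaus.
#' @return A data.frame with columns `time_s`, `delta_lbs`, `pre_plateau_lbs`,
#'   `post_plateau_lbs`, `person_label` (all `"unassigned"`; see
#'   [attribute_persons()]).
#' @export
detect_weight_events <- function(total, min_step_lbs = 5, settle_s = 3,
                                 guard_s = 0.8) {
  stopifnot(min_step_lbs > 0, settle_s > 0)
  dec <- decimate_median(total$x, total$t, total$fs, out_fs = 10)
  y <- dec$x; tt <- dec$t
  n <- length(y)
  empty <- data.frame(time_s = numeric(0), delta_lbs = numeric(0),
                      pre_plateau_lbs = numeric(0),
                      post_plateau_lbs = numeric(0),
                      person_label = character(0))
  if (n < 30) return(empty)
  m <- stats::runmed(y, 3)
  span <- 5L # +-0.5 s differential at 10 Hz
  ds <- rep(0, n)
  idx <- (span + 1L):(n - span)
  ds[idx] <- m[idx + span] - m[idx - span]
  hit <- abs(ds) >= min_step_lbs
  if (!any(hit)) return(empty)
  # cluster contiguous candidates (gap <= 1 s) and localise each at max |ds|
  hits <- which(hit)
  brk <- c(0, which(diff(hits) > 10), length(hits))
  cand <- vapply(seq_len(length(brk) - 1L), function(k) {
    cl <- hits[(brk[k] + 1L):brk[k + 1L]]
    cl[which.max(abs(ds[cl]))]
  }, integer(1))
  cand_t <- tt[cand]
  ev <- list()
  for (k in seq_along(cand)) {
    tk <- cand_t[k]
    prev_t <- if (k > 1) cand_t[k - 1] else -Inf
    next_t <- if (k < length(cand)) cand_t[k + 1] else Inf
    pre_lo <- max(tt[1], tk - guard_s - settle_s, prev_t + guard_s)
    pre_hi <- tk - guard_s
    post_lo <- tk + guard_s
    post_hi <- min(tt[n], tk + guard_s + settle_s, next_t - guard_s)
    pre <- y[tt >= pre_lo & tt <= pre_hi]
    post <- y[tt >= post_lo & tt <= post_hi]
    if (length(pre) < 5 || length(post) < 5) next
    delta <- median(post) - median(pre)
    if (abs(delta) < min_step_lbs) next
    # plateau flatness: a sloped ramp is not a step
    spread <- max(diff(quantile(pre, c(0.1, 0.9), names = FALSE)),
                  diff(quantile(post, c(0.1, 0.9), names = FALSE)))
    if (spread > 0.6 * abs(delta)) next
    ev[[length(ev) + 1L]] <-
      data.frame(time_s = tk, delta_lbs = delta,
                 pre_plateau_lbs = median(pre),
                 post_plateau_lbs = median(post),
                 person_label = "unassigned")
  }
  if (!length(ev)) return(empty)
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

# median-bin decimation to a coarser uniform rate (robust to transients)
decimate_median <- function(x, t, fs, out_fs = 10) {
  if (fs <= out_fs) return(list(x = x, t = t))
  per <- max(1L, as.integer(round(fs / out_fs)))
  n <- (length(x) %/% per) * per
  xm <- matrix(x[seq_len(n)], nrow = per)
  tm <- matrix(t[seq_len(n)], nrow = per)
  list(x = apply(xm, 2, median), t = colMeans(tm))
}

#' Attribute weight events to two persons sharing a bed
#'
#' Event magnitudes (entries and exits folded by absolute value) are
#' clustered into at most two groups by exact one-dimensional two-means;
#' each person's weight is the mean magnitude of their events. Events below
#' `min_person_lbs` are treated as objects/pets and excluded.
#'
#' @param events a data.frame from [detect_weight_events()].
#' @param min_person_lbs magnitude gate separating persons from objects.
#' @return A list with `P1`, `P2` (each `list(weight_lbs, sd_lbs, n_events)`;
#'   `P2` is `NULL` for a single occupant) and `events`, a copy of the input
#'   with `person_label` filled in (`P1`/`P2`/`object`).
#' @export
attribute_persons <- function(events, min_person_lbs = 30) {
  ev <- events
  ev$person_label <- ifelse(abs(ev$delta_lbs) < min_person_lbs,
                            "object", "unassigned")
  pe <- which(ev$person_label == "unassigned")
  if (!length(pe)) stop("no person-scale events to attribute")
  m <- abs(ev$delta_lbs[pe])
  one_cluster <- length(m) < 2 ||
    (max(m) - min(m)) <= max(2, 0.02 * mean(m))
  if (one_cluster) {
    ev$person_label[pe] <- "P1"
    return(list(P1 = list(weight_lbs = mean(m), sd_lbs = sd(m),
                          n_events = length(m)),
                P2 = NULL, events = ev))
  }
  sp <- split_two_means(m)
  grp <- sp$assign
  cent <- c(mean(m[grp == 1]), mean(m[grp == 2]))
  for (g in 1:2) {
    mg <- m[grp == g]
    if (length(mg) > 1 &&
        (max(mg) - min(mg)) > max(4, 0.05 * cent[g]))
      stop(sprintf(
        "ambiguous clustering (>2 plausible weight groups); magnitudes: %s",
        paste(sprintf("%.1f", sort(m)), collapse = ", ")))
  }
  # P1 = cluster of the earliest person event (label order is arbitrary)
  first_grp <- grp[which.min(ev$time_s[pe])]
  lab <- ifelse(grp == first_grp, "P1", "P2")
  ev$person_label[pe] <- lab
  mk <- function(g) {
    mg <- m[lab == g]
    list(weight_lbs = mean(mg), sd_lbs = if (length(mg) > 1) sd(mg) else 0,
         n_events = length(mg))
  }
  list(P1 = mk("P1"), P2 = mk("P2"), events = ev)
}

# exact 1-D two-means: best split of sorted values minimising within-SS
split_two_means <- function(m) {
  o <- order(m)
  s <- m[o]
  n <- length(s)
  best <- NULL; best_ss <- Inf
  for (k in 1:(n - 1)) {
    a <- s[1:k]; b <- s[(k + 1):n]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (ss < best_ss) { best_ss <- ss; best <- k }
  }
  assign <- integer(n)
  assign[o[1:best]] <- 1L
  assign[o[(best + 1):n]] <- 2L
  list(assign = assign, within_ss = best_ss)
}

#' Bed-occupancy classification from the total-weight series
#'
#' In-bed wherever the tare-subtracted total meets `person_threshold_lbs`,
#' with hysteresis so small fluctuations at the threshold do not chatter,
#' plus a per-epoch binary series on the 30 s grid.
#'
#' @param total a [bed_series()] of total load in lbs.
#' @param empty_bed_lbs empty-bed (tare) load; must be supplied or estimated
#'   from a declared empty interval via `empty_interval_s`.
#' @param person_threshold_lbs occupancy threshold above tare (default 50).
#' @param hysteresis_lbs drop below `threshold - hysteresis` required to
#'   leave the in-bed state.
#' @param epoch_s epoch length for the binary series.
#' @param empty_interval_s optional `c(start, end)` over which to estimate
#'   the tare as the median total.
#' @return A list with `intervals` (data.frame `start_s`, `end_s`),
#'   `epochs` (data.frame `epoch_start_s`, `in_bed`) and `empty_bed_lbs`.
#' @export
occupancy <- function(total, empty_bed_lbs = NULL, person_threshold_lbs = 50,
                      hysteresis_lbs = 5, epoch_s = 30,
                      empty_interval_s = NULL) {
  if (is.null(empty_bed_lbs)) {
    if (is.null(empty_interval_s))
      stop("calibration error: supply `empty_bed_lbs` or `empty_interval_s`")
    sel <- total$t >= empty_interval_s[1] & total$t <= empty_interval_s[2]
    if (!any(sel)) stop("calibration error: empty interval contains no samples")
    empty_bed_lbs <- median(total$x[sel])
  }
  ex <- total$x - empty_bed_lbs
  hi <- person_threshold_lbs
  lo <- person_threshold_lbs - hysteresis_lbs
  state <- logical(length(ex))
  cur <- FALSE
  for (i in seq_along(ex)) {
    if (!cur && ex[i] >= hi) cur <- TRUE
    else if (cur && ex[i] < lo) cur <- FALSE
    state[i] <- cur
  }
  r <- rle(state)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  iv <- data.frame(start_s = total$t[starts[r$values]],
                   end_s = total$t[ends[r$values]])
  ep_start <- seq(0, max(total$t), by = epoch_s)
  in_bed <- vapply(ep_start, function(e0) {
    sel <- total$t >= e0 & total$t < e0 + epoch_s
    mean(state[sel]) > 0.5
  }, logical(1))
  list(intervals = iv,
       epochs = data.frame(epoch_start_s = ep_start, in_bed = in_bed),
       empty_bed_lbs = empty_bed_lbs)
}

#' Daily weights from attributed events
#'
#' The day's weight is the robust average (median) of the magnitudes of that
#' day's person-attributed entry and exit events. Days are noon-to-noon; days
#' without events are absent from the output, never reported as zero.
#'
#' @param events a data.frame of events whose `person_label` is filled in
#'   (see [attribute_persons()]); only labels in `person` are used.
#' @param occupancy optional result of [occupancy()]; when given, only events
#'   within 5 s of an occupancy-interval boundary are used.
#' @param session_start wall-clock start of the session (`POSIXct` or seconds
#'   since the epoch); defaults to the epoch.
#' @param person which labels count as the monitored patient.
#' @return A data.frame `date`, `weight_lbs`, `n_events`.
#' @export
daily_weight <- function(events, occupancy = NULL, session_start = 0,
                         person = c("P1", "unassigned")) {
  t0 <- as.numeric(session_start)
  ev <- events[events$person_label %in% person, , drop = FALSE]
  if (!is.null(occupancy)) {
    bnd <- c(occupancy$intervals$start_s, occupancy$intervals$end_s)
    keep <- vapply(ev$time_s, function(x) any(abs(bnd - x) <= 5), logical(1))
    ev <- ev[keep, , drop = FALSE]
  }
  if (!nrow(ev))
    return(data.frame(date = as.Date(character(0)), weight_lbs = numeric(0),
                      n_events = integer(0)))
  abs_t <- t0 + ev$time_s
  day <- floor((abs_t - 43200) / 86400) # noon-to-noon day index
  agg <- lapply(split(seq_len(nrow(ev)), day), function(ii) {
    data.frame(weight_lbs = median(abs(ev$delta_lbs[ii])),
               n_events = length(ii))
  })
  out <- do.call(rbind, agg)
  out$date <- as.Date(as.numeric(names(agg)) + 1, origin = "1970-01-01")
  rownames(out) <- NULL
  out[, c("date", "weight_lbs", "n_events")]
}

#' Convert a volume of water to pounds
#'
#' Convenience for the weight-sensitivity protocol: a water aliquot of
#' `ml` millilitres at `density_g_per_ml` converts to pounds
#' (1 lb = 453.59237 g), so the canonical 15 mL aliquot is 0.033 lbs.
#'
#' @param ml volume in millilitres.
#' @param density_g_per_ml density in g/mL (1 for water).
#' @return Mass in pounds.
#' @export
ml_water_to_lbs <- function(ml, density_g_per_ml = 1) {
  ml * density_g_per_ml / 453.59237
}
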