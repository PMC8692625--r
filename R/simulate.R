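#' Person specification for the bed-signal simulator
#'
#' Describes one sleeper: total body weight, the projection of that load onto
#' the four bed legs, the respiratory waveform (a brisk linear inspiratory
#' upstroke followed by an exponential expiratory decay), the cardiac beat
#' train, respirophasic beat-amplitude coupling, and entry/exit times.
#'
#' @param weight total body weight in lbs.
#' @param projection nonnegative leg-load fractions (one per channel) summing
#'   to 1.
#' @param resp_rate respiratory rate in breaths/min (6-40).
#' @param resp_amplitude peak respiratory load excursion in lbs.
#' @param inspiration_fraction fraction of the breath period spent in the
#'   linear inspiratory upstroke (0-1).
#' @param expiry_tau expiratory decay time constant in seconds.
#' @param heart_rate heart rate in beats/min (40-180).
#' @param bcg_amplitude peak amplitude of one cardiac recoil complex in lbs;
#'   the default 0.15 lbs corresponds to a typical ~0.7 N J-wave recoil force.
#' @param coupling_gain multiplier applied to beats that begin during
#'   inspiration (1 = no respirophasic coupling).
#' @param entry_s,exit_s bed entry and exit times in seconds; `exit_s = Inf`
#'   means in bed until session end.
#' @param hr_jitter_sd standard deviation of multiplicative inter-beat
#'   interval jitter; the default 0.02 reflects normal heart-rate
#'   variability (0 = metronomic).
#' @return An object of class `person_spec`.
#' @export
person_spec <- function(weight, projection = c(0.3, 0.3, 0.2, 0.2),
                        resp_rate = 15, resp_amplitude = 0.5,
                        inspiration_fraction = 0.3, expiry_tau = 1.2,
                        heart_rate = 65, bcg_amplitude = 0.15,
                        coupling_gain = 1, entry_s = 0, exit_s = Inf,
                        hr_jitter_sd = 0.02) {
  stopifnot(weight > 0, all(projection >= 0))
  if (abs(sum(projection) - 1) > 1e-9) stop("`projection` must sum to 1")
  if (resp_rate <= 6 || resp_rate >= 40) stop("`resp_rate` must lie in (6, 40) bpm")
  if (heart_rate <= 40 || heart_rate >= 180) stop("`heart_rate` must lie in (40, 180) bpm")
  if (inspiration_fraction <= 0 || inspiration_fraction >= 1)
    stop("`inspiration_fraction` must lie in (0, 1)")
  structure(list(weight = weight, projection = projection,
                 resp_rate = resp_rate, resp_amplitude = resp_amplitude,
                 inspiration_fraction = inspiration_fraction,
                 expiry_tau = expiry_tau, heart_rate = heart_rate,
                 bcg_amplitude = bcg_amplitude, coupling_gain = coupling_gain,
                 entry_s = entry_s, exit_s = exit_s,
                 hr_jitter_sd = hr_jitter_sd),
            class = "person_spec")
}

#' Apnea specification for the bed-signal simulator
#'
#' Central apneas have no respiratory effort (amplitude exactly zero);
#' obstructive apneas retain a low-amplitude unproductive effort equal to
#' `effort_fraction` of the baseline amplitude.
#'
#' @param start_s onset time in seconds.
#' @param duration_s duration in seconds (> 0).
#' @param kind `"central"` or `"obstructive"`.
#' @param effort_fraction residual effort amplitude as a fraction of baseline;
#'   must be 0 for central apneas and in (0, 0.5] for obstructive ones.
#' @param person 1-based index of the affected person.
#' @return An object of class `apnea_spec`.
#' @export
apnea_spec <- function(start_s, duration_s, kind = c("central", "obstructive"),
                       effort_fraction = if (match.arg(kind) == "central") 0 else 0.2,
                       person = 1) {
  kind <- match.arg(kind)
  stopifnot(duration_s > 0)
  if (kind == "central" && effort_fraction != 0)
    stop("central apneas must have effort_fraction = 0")
  if (kind == "obstructive" && (effort_fraction <= 0 || effort_fraction > 0.5))
    stop("obstructive apneas need effort_fraction in (0, 0.5]")
  structure(list(start_s = start_s, duration_s = duration_s, kind = kind,
                 effort_fraction = effort_fraction, person = person),
            class = "apnea_spec")
}

# run fn with a deterministic, restored RNG state
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# respiratory source waveform: linear rise over fi*T per cycle, then
# exponential decay with time constant tau; unit peak amplitude
resp_waveform <- function(t_rel, period, fi, tau) {
  ph <- t_rel %% period
  rise <- period * fi
  ifelse(t_rel < 0, 0,
         ifelse(ph < rise, ph / rise, exp(-(ph - rise) / tau)))
}

# damped-sinusoid cardiac recoil kernel (~8 Hz, ~0.3 s), unit peak
bcg_kernel <- function(fs, f0 = 8, tau = 0.07, dur = 0.3) {
  s <- seq(0, dur, by = 1 / fs)
  k <- sin(2 * pi * f0 * s) * exp(-s / tau)
  k / max(abs(k))
}

#' Simulate a night of 4-channel bed-sensor data with full ground truth
#'
#' Generates channels as bed tare + per-person static load projected onto the
#' legs + respiratory waveform + cardiac (ballistocardiographic) beat train +
#' optional movement artifacts + slow drift + white sensor noise. Every
#' generated phenomenon is recorded in the returned truth object. Identical
#' seeds give bit-identical output.
#'
#' @param persons list of [person_spec()]s.
#' @param apneas list of [apnea_spec()]s (non-overlapping per person).
#' @param ectopy_times times (s) of premature beats: the preceding inter-beat
#'   interval is halved, the premature beat is attenuated to 50% amplitude and
#'   the post-ectopic beat is amplified by `post_ectopic_gain`.
#' @param noise_sd white sensor noise standard deviation per channel.
#' @param drift_per_hour slow per-channel drift magnitude (units/hour); each
#'   channel drifts linearly at a seeded rate in \[-1, 1\] x this value.
#' @param duration_s session length in seconds.
#' @param seed integer seed; required (no hidden randomness).
#' @param fs sampling rate in Hz.
#' @param tare_lbs static empty-bed load, split equally across channels.
#' @param n_ch number of channels.
#' @param movements optional data.frame with columns `person`, `start_s`,
#'   `duration_s`: high-amplitude low-frequency artifact bursts after which
#'   the person's projection is permanently redistributed.
#' @param post_ectopic_gain amplitude multiplier of the first post-ectopic
#'   beat.
#' @return A list with elements `frame` (a [sensor_frame()], units lbs) and
#'   `truth` (breath peaks, beat times/amplitudes/phases, entry/exit events,
#'   apnea and movement intervals, the mixing matrix, and the per-person
#'   noise-free source waveforms).
#' @export
simulate_session <- function(persons, apneas = list(), ectopy_times = numeric(),
                             noise_sd = 0.01, drift_per_hour = 0,
                             duration_s = 600, seed, fs = 80,
                             tare_lbs = 120, n_ch = 4, movements = NULL,
                             post_ectopic_gain = 1.4) {
  if (missing(seed)) stop("`seed` is required: the simulator has no hidden randomness")
  if (inherits(persons, "person_spec")) persons <- list(persons)
  if (inherits(apneas, "apnea_spec")) apneas <- list(apneas)
  for (p in persons)
    if (p$entry_s < 0 || p$entry_s >= duration_s)
      stop("person entry time outside the session")
  # overlapping apneas for one person are a specification error
  by_person <- split(apneas, vapply(apneas, `[[`, 0, "person"))
  for (grp in by_person) {
    if (length(grp) < 2) next
    iv <- t(vapply(grp, function(a) c(a$start_s, a$start_s + a$duration_s),
                   numeric(2)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] < iv[-nrow(iv), 2]))
      stop("overlapping apneas specified for one person")
  }
  with_seed(seed, function() {
    n <- as.integer(round(duration_s * fs))
    t <- (seq_len(n) - 1L) / fs
    ch <- matrix(0, n, n_ch)
    kern <- bcg_kernel(fs)
    truth <- list(persons = persons, breath_peaks = list(), beat_times = list(),
                  beat_amplitudes = list(), beat_resp_phase = list(),
                  events = NULL, apneas = NULL, movements = movements,
                  mixing = matrix(0, n_ch, length(persons)),
                  sources = matrix(0, n, length(persons)),
                  fs = fs, duration_s = duration_s, seed = seed)
    ev <- list()
    ap_rows <- list()

    for (pi in seq_along(persons)) {
      p <- persons[[pi]]
      if (length(p$projection) != n_ch)
        stop("projection length must equal the channel count")
      exit <- min(p$exit_s, duration_s)
      inbed <- t >= p$entry_s & t < exit
      trel <- t - p$entry_s
      period <- 60 / p$resp_rate

      # respiration: apnea onsets snap to the breath peak of the containing
      # cycle (the last inspiration completes, then effort stops), and the
      # phase clock restarts with a fresh resumption inspiration at apnea end
      rise <- period * p$inspiration_fraction
      my_ap <- Filter(function(a) a$person == pi, apneas)
      if (length(my_ap))
        my_ap <- my_ap[order(vapply(my_ap, `[[`, 0, "start_s"))]
      seg_start <- p$entry_s
      resp_shape <- numeric(n)
      env <- rep(1, n)
      for (a in my_ap) {
        m <- max(0, round((a$start_s - seg_start - rise) / period))
        a0 <- seg_start + rise + m * period
        b0 <- a0 + a$duration_s
        sel <- t >= seg_start & t < b0
        resp_shape[sel] <- resp_waveform(t[sel] - seg_start, period,
                                         p$inspiration_fraction, p$expiry_tau)
        env[t >= a0 & t < b0] <- a$effort_fraction
        ap_rows[[length(ap_rows) + 1L]] <-
          data.frame(person = pi, start_s = a0, duration_s = a$duration_s,
                     kind = a$kind, effort_fraction = a$effort_fraction)
        seg_start <- b0
      }
      sel <- t >= seg_start & t < exit
      resp_shape[sel] <- resp_waveform(t[sel] - seg_start, period,
                                       p$inspiration_fraction, p$expiry_tau)
      # chest-wall motion is smooth: round the piecewise kinks (double
      # boxcar ~ triangular kernel, C1, cuts energy above ~4 Hz) so the
      # respiratory component leaves no clicks in the cardiac band
      resp_shape <- moving_stat(moving_stat(resp_shape, 0.15, "mean", fs = fs),
                                0.15, "mean", fs = fs)
      resp <- p$resp_amplitude * resp_shape * env * inbed
      # ground-truth breath peaks from the generated shape itself;
      # suppressed peaks (effort <= 0.5 of baseline) are not breaths
      pk_i <- find_peaks_prom(resp_shape, min_dist = 0.5 * period * fs,
                              min_prom = 0.3)
      pk_i <- pk_i[env[pk_i] > 0.5 & inbed[pk_i]]
      truth$breath_peaks[[pi]] <- t[pk_i]

      # beat schedule with seeded jitter and ectopy edits
      ibi <- 60 / p$heart_rate
      nb <- ceiling((exit - p$entry_s) / ibi) + 2L
      ivl <- rep(ibi, nb)
      if (p$hr_jitter_sd > 0)
        ivl <- ivl * exp(rnorm(nb, 0, p$hr_jitter_sd))
      bt <- p$entry_s + cumsum(ivl)
      bt <- bt[bt < exit - 0.35]
      amp <- rep(1, length(bt))
      for (et in ectopy_times) {
        i <- which.min(abs(bt - et))
        if (i < 2 || i >= length(bt)) next
        bt[i] <- bt[i - 1] + 0.5 * (bt[i] - bt[i - 1])
        amp[i] <- amp[i] * 0.5
        amp[i + 1] <- amp[i + 1] * post_ectopic_gain
      }
      # respirophasic coupling: beats beginning on the inspiratory upstroke
      bidx <- pmin(n - 2L, pmax(1L, as.integer(round(bt * fs)) + 1L))
      insp <- resp_shape[bidx + 2L] > resp_shape[bidx]
      amp[insp] <- amp[insp] * p$coupling_gain
      bcg <- numeric(n)
      for (b in seq_along(bt)) {
        i0 <- as.integer(round(bt[b] * fs)) + 1L
        ii <- i0:min(n, i0 + length(kern) - 1L)
        bcg[ii] <- bcg[ii] + amp[b] * p$bcg_amplitude * kern[seq_along(ii)]
      }
      truth$beat_times[[pi]] <- bt
      truth$beat_amplitudes[[pi]] <- amp
      truth$beat_resp_phase[[pi]] <-
        ifelse(insp, "inspiration", "expiration")

      # projection, possibly redistributed after movement artifacts
      proj <- matrix(p$projection, n, n_ch, byrow = TRUE)
      art <- numeric(n)
      if (!is.null(movements) && nrow(movements)) {
        mv <- movements[movements$person == pi, , drop = FALSE]
        cur <- p$projection
        for (m in seq_len(nrow(mv))) {
          i0 <- max(1L, as.integer(round(mv$start_s[m] * fs)) + 1L)
          i1 <- min(n, as.integer(round((mv$start_s[m] + mv$duration_s[m]) * fs)))
          burst <- rnorm(i1 - i0 + 1L, 0, 0.05 * p$weight)
          burst <- stats::filter(burst, rep(1 / 8, 8), sides = 2)
          burst[is.na(burst)] <- 0
          art[i0:i1] <- art[i0:i1] + as.numeric(burst)
          cur <- cur * exp(rnorm(n_ch, 0, 0.2))
          cur <- cur / sum(cur)
          proj[i1:n, ] <- matrix(cur, n - i1 + 1L, n_ch, byrow = TRUE)
        }
      }
      src <- p$weight * inbed + resp + bcg + art * inbed
      ch <- ch + proj * src
      truth$mixing[, pi] <- p$projection
      truth$sources[, pi] <- resp
      ev[[length(ev) + 1L]] <-
        data.frame(person = pi, time_s = p$entry_s, delta_lbs = p$weight)
      if (exit < duration_s)
        ev[[length(ev) + 1L]] <-
          data.frame(person = pi, time_s = exit, delta_lbs = -p$weight)
    }

    ch <- ch + tare_lbs / n_ch
    if (drift_per_hour != 0) {
      rates <- runif(n_ch, -1, 1) * drift_per_hour
      ch <- ch + outer(t / 3600, rates)
    }
    if (noise_sd > 0) ch <- ch + matrix(rnorm(n * n_ch, 0, noise_sd), n, n_ch)

    truth$events <- if (length(ev)) {
      e <- do.call(rbind, ev)
      e[order(e$time_s), ]
    } else data.frame(person = integer(0), time_s = numeric(0),
                      delta_lbs = numeric(0))
    truth$apneas <- if (length(ap_rows)) do.call(rbind, ap_rows) else
      data.frame(person = integer(0), start_s = numeric(0),
                 duration_s = numeric(0), kind = character(0),
                 effort_fraction = numeric(0))
    list(frame = sensor_frame(t, ch, units = "lbs", nominal_rate = fs),
         truth = truth)
  })
}

#' Simulate the weight-sensitivity aliquot protocol
#'
#' A glass on the bed receives `n_aliquots` equal water aliquots (canonical
#' size 0.033 lbs, i.e. 15 mL) at fixed intervals, producing a staircase of
#' small steps on top of a constant base load.
#'
#' @param base_load constant load in lbs (bed tare plus glass).
#' @param aliquot_lbs size of each step in lbs.
#' @param n_aliquots number of aliquots.
#' @param interval_s spacing between aliquots in seconds.
#' @param noise_sd per-channel white noise sd in lbs.
#' @param seed integer seed.
#' @param fs sampling rate in Hz.
#' @param lead_s quiet time before the first aliquot.
#' @return A list with `frame` and `truth` (a data.frame of step times/sizes).
#' @export
simulate_aliquot_test <- function(base_load, aliquot_lbs = 0.033,
                                  n_aliquots = 5, interval_s = 20,
                                  noise_sd = 0.005, seed, fs = 80,
                                  lead_s = 20) {
  stopifnot(aliquot_lbs > 0, n_aliquots >= 1)
  if (missing(seed)) stop("`seed` is required")
  steps <- data.frame(time_s = lead_s + interval_s * (seq_len(n_aliquots) - 1L),
                      delta_lbs = aliquot_lbs)
  duration <- lead_s + interval_s * n_aliquots
  sim <- simulate_steps(steps, duration_s = duration, base_load = base_load,
                        noise_sd = noise_sd, seed = seed, fs = fs)
  sim$truth$aliquot_lbs <- aliquot_lbs
  sim
}

#' Simulate the two-person entry/exit simultaneity protocol
#'
#' Eight step events with uniform spacing `interval_s`:
#' P1 in, P2 in, P1 out, P2 out, then the sequence repeated with the two
#' persons exchanged (P2 in, P1 in, P2 out, P1 out). The canonical protocol
#' spacings are 30, 15, 10 and 5 s.
#'
#' @param p1,p2 [person_spec()]s (only their weights are used; the protocol is
#'   a static weighing manoeuvre).
#' @param interval_s spacing between consecutive events in seconds.
#' @param seed integer seed.
#' @param noise_sd per-channel white noise sd in lbs.
#' @param fs sampling rate in Hz.
#' @param lead_s quiet margin before the first and after the last event.
#' @return A list with `frame` and `truth` (`events`: 8 rows of person, time,
#'   signed delta).
#' @export
simulate_simultaneity <- function(p1, p2, interval_s = 30, seed,
                                  noise_sd = 0.02, fs = 80, lead_s = 15) {
  stopifnot(interval_s > 0)
  if (missing(seed)) stop("`seed` is required")
  w1 <- p1$weight; w2 <- p2$weight
  who <- c(1, 2, 1, 2, 2, 1, 2, 1)
  sgn <- c(1, 1, -1, -1, 1, 1, -1, -1)
  steps <- data.frame(time_s = lead_s + interval_s * (0:7),
                      delta_lbs = sgn * ifelse(who == 1, w1, w2),
                      person = who)
  duration <- 2 * lead_s + interval_s * 7
  sim <- simulate_steps(steps, duration_s = duration, base_load = 120,
                        noise_sd = noise_sd, seed = seed, fs = fs)
  sim
}

# shared staircase generator: piecewise-constant total load split across 4
# channels with a position-dependent split, plus white noise
simulate_steps <- function(steps, duration_s, base_load, noise_sd, seed,
                           fs = 80, n_ch = 4) {
  with_seed(seed, function() {
    n <- as.integer(round(duration_s * fs))
    t <- (seq_len(n) - 1L) / fs
    total <- rep(base_load, n)
    for (i in seq_len(nrow(steps))) {
      total[t >= steps$time_s[i]] <-
        total[t >= steps$time_s[i]] + steps$delta_lbs[i]
    }
    split <- runif(n_ch); split <- split / sum(split)
    ch <- outer(total, split)
    if (noise_sd > 0) ch <- ch + matrix(rnorm(n * n_ch, 0, noise_sd), n, n_ch)
    list(frame = sensor_frame(t, ch, units = "lbs", nominal_rate = fs),
         truth = list(events = steps, base_load = base_load,
                      fs = fs, duration_s = duration_s, seed = seed))
  })
}

#' Simulate repeated placements of one static load for joint calibration
#'
#' A constant load is recorded at several bed positions (canonically a 25 lbs
#' weight moved from the middle to the four corners). Each channel reads the
#' local load fraction divided by its true gain, so the gain-weighted channel
#' sum reconstructs the load exactly before noise.
#'
#' @param load_lbs the constant load.
#' @param true_gains per-channel true correction gains (ground truth for
#'   calibration recovery).
#' @param n_positions number of placements.
#' @param duration_s recording length per placement.
#' @param noise_sd per-channel white noise sd.
#' @param seed integer seed.
#' @param fs sampling rate in Hz.
#' @return A list with `frames` (list of [sensor_frame()]s, one per
#'   placement) and `truth` (`gains`, `load_lbs`, per-placement load
#'   fractions).
#' @export
simulate_placements <- function(load_lbs = 25,
                                true_gains = c(1.0, 0.9, 1.1, 1.05),
                                n_positions = 5, duration_s = 5,
                                noise_sd = 0.005, seed, fs = 80) {
  if (missing(seed)) stop("`seed` is required")
  n_ch <- length(true_gains)
  with_seed(seed, function() {
    # middle then corners: distinct, well-spread load fractions
    fracs <- matrix(runif(n_positions * n_ch, 0.05, 1), n_positions, n_ch)
    fracs <- fracs / rowSums(fracs)
    n <- as.integer(round(duration_s * fs))
    t <- (seq_len(n) - 1L) / fs
    frames <- lapply(seq_len(n_positions), function(p) {
      ch <- matrix(rep(load_lbs * fracs[p, ] / true_gains, each = n), n, n_ch)
      if (noise_sd > 0) ch <- ch + matrix(rnorm(n * n_ch, 0, noise_sd), n, n_ch)
      sensor_frame(t, ch, units = "raw_AU", nominal_rate = fs)
    })
    list(frames = frames,
         truth = list(gains = true_gains, load_lbs = load_lbs,
                      fractions = fracs, seed = seed))
  })
}
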