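---
title: "Methods: passive weight and cardiopulmonary monitoring from under-bed force sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: passive weight and cardiopulmonary monitoring from under-bed force sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedsignals)
```

# The measurement problem

A force sensor beneath each leg of a bed turns the bed into a scale that is
always on. The summed load tracks total body weight; the millisecond-scale
redistribution of load across the legs carries the mechanics of breathing
(chest-wall motion) and of each heartbeat (the ballistocardiogram, BCG).
`bedsignals` implements the full analysis stack for such recordings —
calibration, weight and occupancy, respiratory and cardiac rates, apnea
detection, two-person source separation, and long-term aggregation — together
with a seeded simulator that generates recordings with complete ground truth,
so that every stage is testable without hardware.

All signal paths assume the canonical configuration: 4 channels sampled at a
nominal 80 Hz, in digitizer units (AU) or pounds after calibration.

# Calibration and weight

**Joint gain fitting.** The four load cells have slightly different
sensitivities. Because the *total* load is invariant to where on the bed a
load rests, per-channel gains $g_j$ are fitted by minimising, in the
least-squares sense, the variance of the gain-weighted channel sum across
repeated placements of one constant load. A common rescaling of all gains is
unidentifiable, so channel 1 is the gauge reference with $g_1 = 1$; a channel
whose reading does not vary across placements makes the design degenerate and
is reported as an error rather than silently regularised.

**Two-point affine map.** AU convert to pounds through the affine map fixed
by an empty-bed reading (0 lbs) and a known reference load, exactly at both
anchors.

**Step events.** Weight changes (entries, exits, objects) are extracted from
the total-load series as step events: candidate transitions where a
short-scale median differential exceeds `min_step_lbs`, with each event's
delta measured as the difference of flanking plateau medians (3 s plateaus, a
0.8 s guard band around the transition). Plateau flatness is enforced so a
continuous ramp yields no events. The default `min_step_lbs` is 5 lbs for
person-scale work and ~0.02 lbs in high-sensitivity mode, which resolves the
0.033 lbs water-aliquot staircase of the sensitivity protocol. Events under
30 lbs are labelled objects/pets and excluded from person attribution; this
magnitude gate is a heuristic, not a validated rule.

**Two-person attribution.** Event magnitudes are clustered by exact
one-dimensional two-means; each person's weight is the mean magnitude of
their cluster. More than two plausible clusters raise an ambiguity error
listing the magnitudes. The simultaneity protocol (8 alternating entry/exit
steps) is recovered to better than 1% down to 5 s between events.

# Respiratory analysis

Channels are band-passed to 0.167–1.5 Hz with a 4th-order Butterworth filter
applied forward–backward (`signal::filtfilt`), i.e. zero phase, so peak
timing is preserved. The filter order is a package choice; zero-phase
application matters because inter-peak intervals are the rate estimator's
raw material.

**Sliding-window PCA composite.** Within non-overlapping 12.5 s windows the
channel covariance is formed and the leading eigenvector's unit-norm
loadings combine the channels into a single respiratory source signal. Note
the combination weights are the leading eigen*vector* loadings — that is the
linear combination that reconstructs the dominant source; eigen*values*
would not define a combination. The loading sign is set so the
highest-variance channel loads positively, and adjacent windows are
crossfaded over 0.5 s. The hop equals the window (deterministic, no
overlap); a zero-variance window inherits the previous loadings.

**Breath peaks and rates.** Peaks are searched only inside steady
(movement-free) regions — maximal runs where a moving variance stays below
threshold, at least 10 s long for respiration (5 s for BCG). The default
threshold is adaptive, 4 x the 10th percentile of the variance series.
Peak finding uses a topographic-prominence gate (25% of the region's
amplitude scale) plus a minimum spacing. Breathing slower than ~10/min has
its fundamental below the 0.167 Hz band edge, leaving harmonic double-humps
per breath; the breath period estimated from the signal's autocorrelation
(restricted to plausible-rate lags, taking the smallest strong-peak lag so a
multiple of the period is never chosen) sets a half-period spacing floor
that keeps one peak per breath. Rates are computed every 30 s as 60 / median
inter-peak interval within a centered 5-min window; an epoch is invalid with
fewer than 2 peaks or more than 45 s of unsteady physiology in its window.
The median makes single apneas invisible to the rate — by design.

**Apneas.** Apneas are runs where the respiratory amplitude envelope falls
below 50% of the local baseline for *more than* 10 s. The coarse envelope is
a 2 s moving RMS bridged by a 3 s moving maximum (the maximum spans the
within-breath RMS dip of the expiratory decay). Because the whole chain is
zero-phase, edge energy spreads symmetrically, and the unbiased boundary is
the half-level crossing of short-time power between the in-event and
flanking levels; the residual crossing bias caused by the specific shape of
the edge (a breath truncated at its peak; a fresh resumption inspiration) is
removed by self-calibration — the detector folds the flanking breathing into
a mean cycle-power profile, reconstructs each edge synthetically, and
subtracts the offset its own rule produces on that reconstruction. Durations
are recovered within ±0.25 s over 11–81 s events in the simulator.
Classification: residual effort below 5% of baseline is central, 5–50% is
obstructive, and events without flanking baseline are unclassified. The
beating heart leaks its fundamental (≥ 0.8 Hz above ~50 bpm) into the
respiratory band, so effort is measured after subtracting the 0.8–1.5 Hz
sub-band power; the residual band-edge ringing of flanking breaths is
handled by taking the cleanest quartile of the interior power. The 50%
envelope threshold and the 5% central/obstructive split are package
choices; only the >10 s duration rule is inherited from the field.

**Periodic breathing.** The envelope's autocorrelation is scanned for its
first secondary peak; a peak of at least 0.5 at a lag above 30 s flags
periodic (Cheyne-Stokes-like) breathing and returns the cycle length. Using
the *first* peak avoids flagging harmonics of benign shorter-cycle
modulation. At least 10 min of signal is required.

# Ballistocardiography

The single-peak BCG converts raw recoil signals into one positive energy
hump per heartbeat: per-channel bandpass 5–50 Hz (1–50 Hz in amplitude
mode), 50 ms moving mean, 150 ms moving variance, channel summation, final
1–50 Hz bandpass. At 80 Hz sampling a 50 Hz cutoff exceeds Nyquist and is
clipped to 0.99 x Nyquist with a warning. The smoothing windows are package
choices sized to span one recoil complex without merging beats at 180 bpm.

Beat detection gates candidates at 20% of the beat-scale prominence. Sample
quantiles underestimate the scale of a sparse pulse train, so the anchor is
the (k/2)-th largest candidate prominence with k = duration/1.5 s (at least
that many true beats exist when rates are above 40 bpm). The final 1 Hz
highpass produces rebound lobes between beats — strongest at low rates,
where the beat fundamental falls below the cutoff — so the inter-beat
period estimated from the autocorrelation sets a half-period spacing floor.
Beat times and heights are refined to sub-sample precision by parabolic
vertex interpolation, which removes the sampling-grid quantisation
otherwise visible in the rate (the 80 Hz grid quantises inter-beat intervals
to 12.5 ms).

**Amplitude analytics.** The moving variance is quadratic in recoil
amplitude (doubling the signal quadruples peak heights), so the coupling and
post-ectopy analytics work on `beat_magnitude()` — the square root of the
single-peak height — which restores amplitude scale. Respirophasic coupling
labels each beat by the respiratory phase at its onset: inspiration on the
briskly rising limb of the composite (slope above 15% of the strong-upstroke
slope), expiration on the falling/flat limb, `unknown` in the narrow
ambiguous corners; the single-peak energy maximum lags mechanical onset by
about the complex's rise time (~0.1 s), which is subtracted before reading
the phase. Significance is a two-sided Mann-Whitney test. The post-ectopy
ratio compares the first beat after an ectopic run — taken as the largest
beat inside the compensatory window, so residual lobes of the ectopic are
not mistaken for it — against the mean of the 3 preceding beats.

A known residual: additive sensor-noise energy biases measured beat
magnitudes toward each other (a regression-to-the-mean of ratios), about
-2% on the coupling ratio at beat-peak SNR ~9 and growing as SNR drops.
Amplitude analytics should be read as slight underestimates at low SNR.

# Two-person respiratory demixing

Respiratory sources of two sleepers are modelled as latent signals evolving
stochastically and continuously — each a 2-dimensional damped-oscillator
block in a linear-Gaussian state-space model — mixed into the channels by an
unknown linear operator with additive per-sensor (diagonal) Gaussian noise:

$$x_t = A x_{t-1} + w_t,\quad w_t \sim N(0, Q), \qquad
  y_t = C x_t + v_t,\quad v_t \sim N(0, R).$$

Maximum-likelihood estimation is by expectation-maximization: the E-step is
an exact Kalman filter plus Rauch-Tung-Striebel fixed-interval smoother
(implemented in C++; verified against a dense joint-Gaussian solve to
1e-8), and the M-step updates the transition blocks, mixing operator,
block-diagonal process covariance and diagonal observation covariance in
closed form. The log-likelihood is non-decreasing by construction and a
decrease beyond numerical slack raises an internal error rather than being
silenced. Convergence: relative log-likelihood change below 1e-6, at most
200 iterations, 3 seeded jittered restarts by default. The transition is
estimated by default; `estimate_transition = FALSE` keeps the initialised
dynamics.

Initialisation matters more than iteration count here. Each sleeper's
respiratory fundamental marks its own projection pattern, so the mixing
columns are initialised from the cross-channel DFT pattern at the two
dominant spectral peaks and the oscillator frequencies from those peak
frequencies; PCA loadings are the fallback when distinct peaks cannot be
found. With this start, 10-minute two-sleeper mixtures at 12 and 17
breaths/min are demixed with source correlations above 0.99 against truth.

Gauges are fixed explicitly: sources are normalised to unit variance; the
sign is chosen so inspiration points up (a respiratory waveform has positive
skew — brisk upstroke, shallow decay); labels are arbitrary. Since the
respiratory band tops out at 1.5 Hz, estimation runs on channels decimated
to 5 Hz. When the two mixing columns are nearly collinear (one sleeper, or
identical projections) the fit is flagged with a warning and the sources are
re-gauged in channel space so the first carries the common direction and the
second only the orthogonal residual — a lone sleeper's harmonics are not
reported as a second person.

`peak_timing_error()` matches reference breath peaks to source peaks within
half the median breath period and summarises absolute offsets; on simulated
pairs the error against the correct reference is strictly below the error
against the other sleeper's reference in 20 of 20 seeds.

# Longitudinal aggregation

Plausibility filters are strict, exactly as printed: respiratory epochs with
6 < bpm < 40 and cardiac epochs with 60 < bpm < 120 are kept; boundary
values are excluded. Daily summaries run noon-to-noon; days without valid
epochs report missing values, never zero. Percent time-in-bed is the
fraction of 30 s epochs classified occupied (threshold 50 lbs above tare
with 5 lbs hysteresis). Heatmap export reshapes epochs into a
2880-slot x day matrix with display floors (10 bpm respiratory, 60 bpm
cardiac) emitted as missing; the reshape is lossless. The display floor and
the plausibility filter are configured independently. Timestamps are
wall-clock; the caller supplies the session start and implicitly the zone.

# The simulator and what passing tests mean

`simulate_session()` generates channels as bed tare + per-person static load
projected onto the legs + respiratory waveform + cardiac beat train +
optional movement artifacts + slow drift + white sensor noise, with full
ground truth and bit-identical output for identical seeds. Its defaults are
the package's study conditions:

* Respiration: a linear inspiratory upstroke over 30% of the breath period
  followed by exponential expiratory decay (time constant 1.2 s), amplitude
  0.5 lbs. The piecewise shape is rounded by a short triangular kernel
  (~4 Hz corner) because real chest-wall motion is smooth; without it the
  shape's kinks inject artificial clicks into the cardiac band.
* Apneas: onset snaps to the breath peak of the containing cycle (the last
  inspiration completes, then effort stops) and breathing resumes with a
  fresh inspiration at the scheduled end — the physiologic resumption
  breath. Central apneas have exactly zero effort; obstructive ones retain
  `effort_fraction` of baseline amplitude.
* Cardiac: a damped-sinusoid recoil kernel (~8 Hz, ~0.3 s) at 0.15 lbs peak
  (a typical ~0.7 N J-wave recoil force), inter-beat jitter 2% (normal
  heart-rate variability; a metronomic heart phase-locks artificially to
  the breath cycle and the sampling grid). Ectopy halves the preceding
  interval, attenuates the premature beat to 50% and amplifies the
  post-ectopic beat by 1.4; respirophasic coupling multiplies inspiratory
  beats by `coupling_gain`. These values exercise the analytics and are not
  claimed physiologic.
* Movement artifacts: 1–5 s low-frequency bursts followed by a permanent
  redistribution of the person's projection vector.

The simulator emulates stationary, well-separated physiology with Gaussian
sensor noise. It does not emulate real mattress mechanics, posture-dependent
waveform morphology changes, sensor nonlinearity, network dropouts, or
pathological waveform variety; passing tests demonstrate algorithmic
correctness under the stated model, not clinical performance. Validation
problem sizes are desk-scale by choice: nights of 8–12 minutes, 20-seed
demixing batches, and daily summaries built from directly constructed epoch
streams rather than 90-day raw simulations.

# Numerical choices and degenerate inputs

* Filters: Butterworth order 4, forward-backward; upper cutoffs at or above
  Nyquist are clipped to 0.99 x Nyquist with a warning; DC is always
  removed. Irregular sampling should be resampled to the nominal grid before
  filtering; frames reject non-monotonic timestamps outright.
* Moving statistics use shrunken centered windows at the edges, output
  length equals input length, and the variance uses the n-1 denominator.
* EM regularisation: near-singular sufficient statistics receive a
  proportional ridge; process-noise variances are floored at 1e-12; a
  transition estimate with spectral radius above 1 is contracted to the
  unit disc.
* Empty inputs return empty results (no events, no regions, no peaks);
  genuinely unanswerable requests (no flanking baseline, fewer than 10
  matched peaks, under 10 min for periodic breathing) are reported as
  unclassified/not evaluable rather than guessed.

# Known limitations

* The apnea boundary self-calibration assumes reasonably stationary flanking
  breathing; crescendo-decrescendo flanks will blur boundaries.
* Beat-amplitude analytics underestimate contrast at low SNR (see above).
* Bradycardia below ~42 bpm overlaps the cardiac sub-band used to separate
  heartbeat leakage from respiratory effort during apnea classification.
* Two-person BCG (cardiac) demixing is out of scope; the state-space
  demixer addresses respiration only.
* HDF5 frame I/O is not built; the CSV dialect is the interchange format.
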