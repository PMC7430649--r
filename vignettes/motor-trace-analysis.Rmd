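---
title: "Models and methods: simulating and analysing loop-extruding motor traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and analysing loop-extruding motor traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmotor)
```

This vignette explains the models implemented in mtmotor, the assumptions
behind them, the tunable parameters and their defaults, and the numerical
and design choices that were genuinely open. It states no empirical result
that the package's tests and acceptance script do not themselves compute.

## 1. Polymer models and the bp ↔ nm conversion

Bead height changes are converted to base pairs through the extension per
base pair of duplex DNA at the applied force. We use the extensible
Marko–Siggia interpolation

$$F = \frac{k_BT}{P}\left[\frac{1}{4(1 - x + F/S)^2} - \frac14 + x -
\frac{F}{S}\right],$$

solved for the fractional extension $x$ by bracketed root finding
(absolute tolerance $10^{-9}$, strictly monotone on the bracket so a
failure to bracket is an error rather than a silent clamp). Defaults are
the standard room-temperature dsDNA values: persistence length $P$ = 50 nm,
crystallographic rise 0.34 nm/bp, stretch modulus $S$ = 1000 pN,
$T$ = 296 K. None of these is measured by a tweezers experiment itself, so
the conversion at 8 pN carries a few-percent systematic uncertainty that
propagates into every length in bp; all four parameters are configurable
through `duplex_elasticity()`.

Single-stranded DNA follows a freely-jointed chain,
$x_{ss}(F) = \ell\,[\coth(Fb/k_BT) - k_BT/(Fb)]$ with Kuhn length
$b$ = 1.5 nm and contour $\ell$ = 0.57 nm/nt. The contour value was chosen
once so that the ssDNA and dsDNA extension-per-residue curves cross
between 5 and 7 pN (numerically at ≈5.9 pN with the defaults), the regime
boundary that separates the two sign conventions of canonical unwinding;
0.56 nm/nt would put the crossover just above 6 pN and violate the
"longer above 6 pN" requirement, so 0.57 is the default.

Force calibration uses the equipartition estimator
$F = k_BT\,\langle z\rangle/\langle\delta x^2\rangle$ on lateral bead
fluctuations. `simulate_bead_fluctuations()` draws independent Gaussian
displacements with exactly that variance; it does not model the bead's
hydrodynamic low-pass filtering, so it validates the estimator's algebra
and sampling error, not camera-bandwidth corrections.

## 2. The stochastic motor simulator

`simulate_trace()` runs a continuous-time state machine per tether —
waiting → unwinding (with pauses and backslides) → rehybridization →
waiting — with exact event-time bookkeeping (competing exponential
clocks), then samples the piecewise-linear motor position onto the 60 Hz
camera grid and adds white Gaussian height noise. There is no per-frame
Euler stepping, so identical seeds give byte-identical traces.

Key modelling choices:

* **Event lengths.** Detachment is position-targeted: each binding event
  draws its total length from an exponential with mean $1/\text{detach
  per bp}$, the constant-per-bp detachment law that makes event-length
  distributions exponential. Lengths exceeding the track are clipped with
  a warning.
* **Per-event rates.** The instantaneous rate is constant within an event
  and drawn between events from a truncated normal (low and medium
  concentration) or a gamma law (high concentration, where the measured
  rate distribution is visibly skewed), with between-event CV 0.5. Draws
  are truncated below 50 bp/s: a motor translocating below the velocity
  threshold of the 3 Hz derivative analysis is invisible to that analysis
  (and to the measured rate distributions the profiles reproduce), and
  sub-threshold events would otherwise occupy long stretches of trace
  that no derivative-based detector can attribute.
* **Pauses and backslides.** Per-event occurrence percentages are
  converted to Poisson entry rates with
  $\lambda = p/((1-p)\,\bar T)$, where $\bar T$ is the mean exposure
  (unwinding duration $\langle L\rangle/v$, or rehybridization duration
  $\langle L\rangle/v_{rehyb}$); for an exponentially distributed exposure
  this reproduces the per-event probability exactly. Pause durations are
  exponential with mean 8 s — per-event pause percentages can only be
  scored from pauses resolvable at the 3 Hz analysis bandwidth, and
  sub-second pauses are invisible there. A backslide retreats at the
  rehybridization speed (default 2000 bp/s, "rapid") to baseline with the
  condition's completeness probability, else to a uniform 10–90 % of the
  current position, and resumes after 0.5 s. Entry clocks run only on
  fresh (first-passage) track: re-unwinding of a stretch that re-annealed
  behind a backslide does not draw new pauses or backslides. This keeps
  the per-event frequencies at their calibrated values and bounds event
  durations; with clocks also running on re-climbs, slow events with
  complete backslides would enter a geometric restart loop and produce
  effectively immortal events.
* **Initiation.** Waiting times are exponential with mean
  $1/(k_{on}[\text{protein}])$. The low- and high-concentration profiles
  encode their per-condition dwell constants (61 s at 30 nM, 11.6 s
  at 163 nM) as effective $k_{on}$ values; the 50 nM profile, which has no
  dwell constant of its own, uses the global $k_{on} = 5.9\times10^5\,
  \mathrm{M^{-1}s^{-1}}$. A single global $k_{on}$ cannot reproduce both
  dwell constants, so the per-condition reading was preferred; the
  cross-concentration hyperbola then recovers a $k_{on}$ a few percent
  below the global value, within the stated tolerance.
* **Nicked substrates.** A top-strand (translocated-strand) nick arrests
  each event at the nick position with Gaussian jitter (SD 100 bp, clipped
  at ±3 SD so arrest positions are strictly bounded), a ~3 s stall, then
  release and rehybridization; a bottom-strand nick is transparent and the
  tether is never released. The nick distance is a free parameter of the
  tether design; the default of 600 bp (about two-thirds of the low-concentration
  processivity) makes arrests the dominant outcome, which is what produces
  the Gaussian — rather than exponential — length distribution that the
  top-nick experiment is designed to show. A nick placed several
  processivities away would be reached by almost no events and the
  distinction would vanish.
* **SSB.** Single-stranded-DNA-binding protein multiplies the
  rehybridization time tenfold and suppresses the backslide entry rate to
  one quarter, reducing backslide-containing events to below one in ten.
* **Noise.** White Gaussian height noise of SD 15 nm per 60 Hz sample
  (≈3.4 nm, ~10 bp after 3 Hz filtering), consistent with the
  equipartition force-recovery checks; linear drift defaults to zero.

What the generator does *not* emulate: multi-motor collisions (the
concentration dependence of rate and pausing is encoded per profile, not
mechanistically), strand switching, nuclease chemistry, bead rotation or
hydrodynamics, and correlated (1/f) instrument noise. Passing the
recovery tests therefore shows that the analysis chain is unbiased for
this event structure under white noise, not that it is robust to every
artefact of real bead data.

## 3. Trace analysis

The raw 60 Hz height is reduced by non-overlapping boxcar means to 3 Hz
(the method's analysis bandwidth; boxcar because nothing sharper is
specified and it is the simplest reproducible choice, recorded in the
`processed_trace` metadata). The baseline is the mode of the height
histogram in 25-bp-equivalent bins — robust to traces that begin
mid-event — and positions are `(baseline − z)/h(F)` in the looping
geometry.

Segmentation classifies each 3 Hz sample by its central-difference
velocity: forward (> `v_min`), backward (< −`v_min`) or stationary. With
the default thresholds the velocity noise is ≈22 bp/s, so `v_min` =
30 bp/s keeps single-sample misclassification common enough that runs of
labels, not samples, are the unit of decision:

* A **motion run** — a forward run of at least `t_min` = 0.5 s whose net
  displacement is consistent with sustained movement
  (≥ max(`v_min`·dur, 50 bp)) — opens or extends an event. On pure-noise
  traces this criterion produced zero false motion runs in 10 ks in the
  package's own calibration, which is what permits `t_min` below the
  1 s one might first choose: at 215 bp/s a 1 s minimum run would discard
  the entire left tail of the exponential length distribution below
  ~215 bp and bias recovered processivity upward by 15–25 %.
* A backward **retreat** is collected across interleaved stationary
  stretches (rehybridization pauses) until baseline is reached or strong
  forward motion (1.5× displacement floor) interrupts; the stricter floor
  prevents marginal two-sample noise excursions inside a rehybridization
  pause from splitting the retreat into a spurious backslide.
* A retreat that fails to reach baseline, or reaches it but is followed by
  a genuine motion run within `backslide_window` = 1.5 s, is attached to
  its parent event as a backslide (complete iff it reached
  `baseline_tol` = 50 bp). The window sits between the simulator's 0.5 s
  restart delay plus detection latency (~0.8–1.1 s) and the shortest
  dwells it could misclassify; at the high-concentration condition
  (mean dwell 11.6 s) some genuine re-initiations inevitably fall inside
  any window and are scored as backslides — the same ambiguity the
  underlying experiment faces.
* **Pauses** are stationary stretches of at least `t_pause` = 1 s whose
  net velocity is below `v_pause`/2; stretches split by single-sample
  noise excursions are merged before scoring, and stationary runs between
  the last forward run and the terminal retreat (pauses that immediately
  precede detachment) are included. Inside retreats even a single
  stationary sample counts: the motor is disengaged there, so there is no
  slow-translocation flicker to reject.
* **Event length** is the maximum position over the event span minus the
  pre-onset level (median of the three samples before motion). When
  detachment follows the last motion run within two samples, the peak —
  clipped by the boxcar window that averages ascent and 2000 bp/s
  rehybridization — is restored by extrapolating the run's interior slope
  to the estimated detachment time. **Pause-excluded rates** use only the
  interior samples of each motion run (boundary windows straddle the
  onset/offset and dilute the velocity); runs shorter than four samples
  fall back on their largest instantaneous velocity, and the rate
  distribution is fitted on events of ≥ 300 bp, below which too few
  filtered samples exist to resolve velocity at all.
* **Dwells** run from the end of each terminal rehybridization to the next
  detected initiation. Every detected initiation delimits a dwell even
  when the ensuing event falls below `min_event_length`, and dwells are
  additionally split at sub-threshold "blips" (excursions above a local
  median + 4·MAD threshold): an event too small to segment still lifts
  the position visibly, and leaving it inside a dwell would merge two
  waiting periods. Dwells shorter than the backslide window are flagged
  `follows_backslide` and excluded from association-rate estimation.

Residual, quantified biases of the chain (measured against ground truth in
the test suite): events shorter than ~50–70 bp are undetectable, which
merges a few percent of dwells; the per-event rate sample is mildly
depleted of fast events whose short duration resists the ≥300 bp
restriction; and chained re-initiations inflate the apparent backslide
frequency at high concentration by a few points. All are within the
package's stated recovery tolerances.

## 4. Distribution fits

`fit_exponential_mean()` is the exponential MLE (mean = sample mean,
SE = mean/√n) with an optional left truncation: detection thresholds
left-truncate observed lengths and dwells, and by memorylessness the decay
constant of a sample observed above a cutoff is the sample mean minus the
cutoff. `truncation = "auto"` estimates the cutoff by the sample minimum —
the estimator the pipeline and the acceptance script use. Each fit also
reports a histogram decay constant (Poisson regression of binned counts on
bin centres over the dense region below the 95th percentile), the
"error of fitting" convention; in replicate calibration it is noisier than
the shifted MLE, which is why it is secondary.

Gaussian/gamma comparison (`fit_rate_distribution`) fits both by maximum
likelihood and prefers the higher R² on a Freedman–Diaconis-binned density
(minimum 8 bins). Near-ties go to the Gaussian, with a 0.02 R² margin: a
high-shape gamma approximates a normal arbitrarily well, so only a clear
advantage argues for it. Gaussian/exponential arrest discrimination
compares log-likelihoods directly. The hyperbolic association fit
$\langle\Delta t\rangle = 1/(k_{on}c)$ is unweighted least squares (no
weighting is stated for the original analysis), linear in $1/k_{on}$ and
solved in closed form; a `weights` argument provides the
inverse-variance-weighted variant.

## 5. Bulk kinetics

Michaelis–Menten, hyperbolic DNA-activation and single-exponential
progress-curve models are fitted by Levenberg–Marquardt nonlinear least
squares; on their own noiseless generator output all three recover
parameters to relative error below $10^{-6}$ (round-trip identity, tested
against a Lineweaver–Burk closed form for the saturation fit). The
generator applies mean-preserving multiplicative lognormal noise (CV 3 %
for rate assays, 5 % for gel-quantified progress curves) to default
designs of 8 log-spaced ATP points (0.05–2 mM), 8 DNA points (0–20 µM
nucleotides) and 8 timepoints over 4 min. Iron stoichiometry follows
Beer–Lambert at 535 nm (ε = 22 369 M⁻¹cm⁻¹) through the assay's
dilution scheme (10 µl of 15 µM protein into a ~143 µl assay volume).

## 6. Problem sizes and determinism

The acceptance script simulates 20 tethers × 2500 s at 30 nM, 18 × 2200 s
at 163 nM, 20 × 3000 s on the bottom-nicked substrate and 10 × 2000 s at
50 nM — several hundred to a thousand events and dwells per condition, so
that sampling error (a few percent) is small against the 10–15 % recovery
tolerances — and runs in well under a minute. Every random stage receives
an explicit seed derived from the single `--seed` argument; identical
seeds give byte-identical traces, tables and reports.

## 7. Known limitations

* The bp scale inherits the WLC parameter uncertainty (§1).
* Derivative-threshold segmentation cannot see events below ~50 bp or
  rates below ~30 bp/s at 3 Hz with 10 bp position noise; changepoint or
  HMM detection is an extension point, deliberately out of scope.
* The canonical (non-looping) geometry near the ss/ds crossover force has
  a vanishing nm-per-bp conversion; `z_to_bp()` refuses to convert there
  rather than amplifying noise without bound.
* Backslide-vs-re-initiation attribution is ambiguous within the
  backslide window for any detector, ours included.
* The event table's `rate_incl_pauses` column exposes the
  including-pauses rate convention for comparison, but all headline rates
  are pause-excluded net displacement over moving time.
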