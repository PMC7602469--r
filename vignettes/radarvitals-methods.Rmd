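---
title: "Methods: radar vital-sign monitoring from raw I/Q to interval series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radar vital-sign monitoring from raw I/Q to interval series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radarvitals)
```

## The measurement model

A continuous-wave Doppler radar under a mattress illuminates the person in
the bed. Chest-wall motion $d(t)$ phase-modulates the reflected carrier, so
the two down-converted baseband channels of one module trace a point on a
circle in the I/Q plane:

$$I(t) = \cos\varphi(t), \qquad Q(t) = \sin\varphi(t), \qquad
\varphi(t) = \frac{4\pi}{\lambda_0}\, d(t) + \varphi_\mathrm{static},$$

with $\lambda_0 \approx 12.5$ mm at 24 GHz. One millimetre of chest motion
therefore sweeps about one radian of phase, which makes millimetre-scale
respiration and micrometre-scale heart sounds both visible in the same
signal. Four modules (A–D, distinct carriers within the 24 GHz ISM band to
avoid crosstalk) span the bed width so at least one module has a good view
regardless of lying position; each module is processed independently and no
cross-module fusion is attempted (deliberately — selecting or combining
modules is a separate problem).

The pipeline has four stages, each usable on its own:

1. **State classification** — label every 2 s window of the raw 8-channel
   data as absent (0), calm (1), bed entry (2), bed exit (3) or on-bed
   movement (4).
2. **Displacement reconstruction** — on every calm section, correct the I/Q
   hardware imperfections by a direct least-squares ellipse fit, then
   demodulate the four-quadrant phase and scale it by $\lambda_0/4\pi$.
3. **Interval extraction** — breath-to-breath intervals from
   positive-to-negative zero crossings of the band-passed displacement;
   interbeat intervals from duration-explicit HSMM segmentation of the
   heart-sound band.
4. **Evaluation** — interval RMSE on a common 1 Hz grid, majority-vote
   windowed confusion matrices, and Gold-code cross-correlation for
   aligning radar and reference clocks.

## State classification

Presence uses a single feature: the per-window standard deviation
$\mathrm{SD} = \sqrt{\sum_n |X_n - \bar X|^2 / (N-1)}$ of each raw channel
over non-overlapping 2 s windows, compared against 0.7 mV. A window counts
as occupied when **more than four of the eight** channels exceed the
threshold; we read that strictly, so exactly four is still absent. Windows
are aligned to $t = 0$; the trailing partial window is dropped.

Movement uses the signal normalized to its first measured value followed by
the absolute first derivative, $y = |\Delta(x/x_1)|$. We interpret
"normalized" as *division* by the first sample: the alternative
(subtraction) would make the two dimensionless thresholds — variance
$> 4\times10^{-8}$, adjacent-window mean change $\geq 4\times10^{-4}$ —
depend on the signal units, which contradicts their stated values. The
derivative series is one sample shorter than the input; the classifier pads
one leading zero so movement and presence windows stay aligned. A channel
flags a window when either feature fires, a module flags when any of its
channels flags, and a window is movement only when **all** modules flag —
chest motion couples into every module, whereas localized disturbances do
not. With fewer than four connected modules, "all" means all connected
modules.

Maximal movement runs are then classified by their context: absence before
and presence after is an entry, the reverse an exit, presence on both sides
an on-bed movement. The nearest non-movement window on each side supplies
the context; at a recording boundary the missing side counts as absent. A
movement run with absence on both sides has no state code in the five-state
scheme; we keep it as on-bed movement (4), a case the all-module rule makes
practically unreachable on real or simulated data.

The presence flag during movement windows is the SD rule's own output: a
large movement drives the channel SDs far above 0.7 mV, which is exactly
what the entry/exit context logic expects.

## Displacement reconstruction

Gain imbalance, DC offsets and quadrature skew deform the ideal unit circle
into a shifted, tilted ellipse. On every calm section we fit the conic by
the direct least-squares method with the ellipse constraint enforced
through the partitioned generalized eigenproblem (the numerically stable
formulation of the Fitzgibbon fit), after centring and isotropically
scaling the data. The normalization map — translate by the centre, rotate
into the ellipse frame, scale the axes, rotate back — is symmetric positive
definite, so composing it with the (linear) distortion gives a proper
rotation of the unit circle: the demodulated phase equals the true phase up
to an additive constant, with no reflection, as long as the distortion
preserves orientation (gain product times the cosine of the skew positive,
true for any physical channel).

Equation (4)'s single-argument arctangent cannot represent phase
excursions beyond half a cycle, so we use the four-quadrant `atan2`
followed by unwrapping (successive differences folded into $[-\pi,\pi]$).
Samples whose normalized radius falls below 0.1 are flagged and their phase
interpolated from neighbours rather than demodulated. The phase reference
is the first sample of the section; only *relative* displacement is
claimed, and the sign convention (increasing phase = decreasing
radar–target distance) is irrelevant to interval extraction.

Conditioning of the fit depends on arc coverage. The measurement protocol
asks the subject for a small calibration movement at the start of each
recording, and the simulator reproduces it (a 5 mm half-cosine excursion
over 8 s, slow enough never to trip the movement thresholds). When a fitted
ellipse is still ill-conditioned (axis ratio above 20), the section falls
back to offset-only correction with a warning instead of failing; whether
to fit on the whole calm section or only the calibration part is not
prescribed anywhere, and we fit on the whole section. The first
`skip_initial_s` seconds (default 20 s, matching the protocol) are excluded
from the *returned* displacement but still feed the fit.

## Respiration intervals

The displacement is block-mean decimated to 10 Hz and band-passed with a
zero-phase 4th-order Butterworth filter, corners 0.07–0.7 Hz (about 4–40
breaths/min). Two numerical choices deserve a note. First, zero-phase
(forward–backward) filtering is used so crossing times are not biased by
group delay; the effective order doubles but the design order stays 4, and
the single-pass response still has its $-3$ dB point at 0.7 Hz. Second, the
decimation target is 10 Hz rather than ~100 Hz: a 0.07 Hz corner at 100 Hz
means a normalized cutoff of $1.4\times10^{-3}$, where the direct-form IIR
recursion of the available filtering routine is numerically unstable
(output diverges); at 10 Hz the same design is comfortably stable, and a
10 Hz grid resolves breathing with two decades to spare. Block-mean
decimation acts as its own boxcar anti-alias filter; the only content near
the new Nyquist is the micrometre-scale heart-sound band, three orders of
magnitude below respiration.

Breath events are the positive-to-negative zero crossings, located by
linear interpolation between the bracketing samples. Crossings lag the
generative breath onsets by a roughly constant fraction of the cycle; that
offset cancels in the intervals.

## Heartbeat intervals

The heart-sound band (default 16–80 Hz, configurable; the exact band is a
free parameter inherited from the heart-sound literature) is extracted with
the same zero-phase Butterworth design. Two envelope features are computed
— the Hilbert envelope and a homomorphic (low-passed log) envelope — each
low-passed, downsampled to 50 Hz frames and z-scored per section. The
feature rate balances duration resolution (20 ms frames) against decoder
cost.

Segmentation uses a four-state hidden semi-Markov model in the strict
cyclic order S1 → systole → S2 → diastole, Gaussian emissions per state,
and truncated discretized-Gaussian duration models, decoded by a
duration-explicit Viterbi recursion. Boundary runs are censored: the first
and last runs are scored by the duration survivor function
$P(D \geq d)$ rather than the point mass, since their true extent is cut by
the observation window. An S1 run that starts at the first frame is
likewise excluded from the onset list. The decoder is verified against
exhaustive enumeration of all duration-feasible labelings on short
sequences.

The model is *self-calibrating*: `default_hsmm_params()` simulates one
minute of clean heart-sound displacement at a given heart-rate prior,
labels frames from the generative onsets (S2 placed at 35% of the cycle),
and estimates all parameters by supervised moments. Duration SDs are
floored at 20 ms and truncation set to mean ± 4 SD so the model tolerates
rate deviations around the prior. This replaces training on a
phonocardiogram corpus, which is out of scope; the published segmenter's
full logistic-regression emission stack is deliberately not reproduced —
two envelope features with Gaussian emissions are the minimal faithful
reading.

Interbeat intervals are successive S1-onset differences, comparable to
ECG R-peak differences up to a constant anchor offset that cancels in the
intervals.

## Interval conditioning and evaluation

Both interval kinds pass the same conditioning chain before comparison: a
median filter of size 5 (edges shrink), a centred moving average of span 6
(even span, so the window extends one extra sample to the right; edges
shrink), then linear interpolation onto the integer-second grid spanning
the events, each interval anchored at its starting event. RMSE is computed
on the overlapping 1 Hz grid of prediction and reference.

State vectors are compared after expanding to a fine grid and majority
voting over 5 s windows; ties resolve to the *higher* state code,
preferring movement over rest — the conservative direction for a monitoring
system. Trailing partial windows are dropped.

Clock alignment between the radar and a wired reference uses a length-1023
Gold code. The preferred pair of degree-10 polynomials is configuration
(no specific pair is mandated anywhere); the default is the widely used
GPS C/A pair $x^{10}+x^3+1$ and $x^{10}+x^9+x^8+x^6+x^3+x^2+1$, whose Gold
combination has three-valued off-peak circular autocorrelation
$\{-65, -1, 63\}$. The lag estimate is the argmax of per-lag-normalized
cross-correlation (minimum overlap 32 samples); a peak below 0.5 raises a
synchronization failure.

## What the simulator emulates — and what it does not

The scenario generator renders a scripted sequence of absent / entry /
rest / on-bed-movement / exit segments into 8 synchronized channels with
per-window ground-truth states and exact event times:

* **Respiration**: raised-cosine cycles (default 15 breaths/min, 4 mm peak
  amplitude, 3% cycle jitter). A raised cosine has the asymmetric
  inhale/exhale feel of real breathing while staying analytic.
* **Heart sounds**: Gaussian-windowed 40 Hz bursts, S1 (default 20 µm,
  120 ms) at the beat onset and S2 (60% amplitude, 100 ms) at 35% of the
  cycle.
* **Movements**: integrated band-limited noise with ~200 mm/s velocity
  scale, i.e. displacement excursions of one to several wavelengths —
  guaranteed phase wrap and comfortable exceedance of both movement
  thresholds.
* **Channels**: per-module static phase uniform in $[0, 2\pi)$ (I and Q of
  one module share it — that is the physics; a per-channel phase error *is*
  the skew distortion), gains of a few mV with up to 10% imbalance, DC
  offsets of 25–40 mV, a few degrees of skew, 2 µV noise. When the bed is
  empty the motion term vanishes and channels carry offset plus noise;
  entry and exit ramp the reflection amplitude with a half-cosine.

Amplitude scales are chosen for *threshold realism* relative to the fixed
published thresholds, since no amplitude statistics of the real hardware
are available: resting channels swing several mV (SD well above 0.7 mV on
essentially all channels), empty-bed noise sits far below it, and the
normalized-derivative features of resting data sit a factor of about 3
below the movement variance threshold while movement transients exceed it
by orders of magnitude. Two scales deviate from the first-guess values one
might pick: channel noise is 2 µV rather than 0.1 mV, and offsets are tens
of mV — with 0.1 mV sample-to-sample noise at 2000 Sa/s, the variance of
the normalized derivative would exceed $4\times10^{-8}$ in *every* window,
including an empty bed, so the published thresholds themselves pin the
noise floor and offset scale of any plausible hardware.

What the simulator does **not** model: antenna patterns and propagation,
mattress permittivity, multi-person scenes, hardware intermodulation
during strong movement, pulse-wave (non-heart-sound) cardiac components,
and amplitude statistics matched to the real device. Passing tests on
synthetic scenarios therefore demonstrate the correctness of the signal
processing given the stated measurement model, not clinical performance on
hospital data.

## Problem sizes and test design

The test suite and the acceptance script simulate at the native 2000 Sa/s
for the scripted classification scenario (~170 s, 34 evaluation windows)
and at 500 Sa/s for vital-sign sections (5-minute sections; 500 Sa/s
comfortably covers the 80 Hz heart-sound corner). The acceptance script
averages five sections per vital sign; the suite's recovery test uses ten
sections spanning 8–30 breaths/min and 55–90 bpm, with the HSMM prior set
to each section's nominal rate, the way an operator would configure a
monitoring run. These sizes keep a full run in tens of seconds while
leaving every statistical margin wide (observed interval RMSEs are an
order of magnitude below the acceptance bounds).

## Known limitations

* The ellipse fit needs arc coverage; without a calibration movement a very
  shallow breather at an unlucky static phase degrades to offset-only
  correction.
* The HSMM decodes best within roughly ±20% of its heart-rate prior; a
  grossly wrong prior mislabels systole/diastole durations.
* Entry/exit context resolves at 2 s window granularity, so one-window
  timing disagreements at movement boundaries are expected (they also
  dominate the residual error of the windowed accuracy).
* The respiration chain reports intervals, not tidal volume; apnea
  detection and volume estimation are out of scope.
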