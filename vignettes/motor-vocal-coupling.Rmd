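---
title: "Event-locked analysis of infant motor-vocal coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-locked analysis of infant motor-vocal coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocmotor)
```

## The scientific question

Infant vocalisations do not happen in a still body: limb movement and vocal
output are temporally coupled, and the balance between arm and leg
involvement reorganises over the first year as posture and motor control
mature. `vocmotor` implements the measurement chain needed to quantify
this coupling from semi-naturalistic recordings: a room microphone
(44,100 Hz WAV), utterance-level annotations of infant vocalisations
(Praat TextGrid), and wrist/ankle-worn 3-axis accelerometers at a nominal
60 Hz.

The dependent measure is the **median acceleration envelope** of each limb
in three windows anchored to each vocalisation onset:

* baseline: $[-2.5, -0.9)$ s (infant silent),
* pre-vocalisation: $[-0.9, 0)$ s,
* during-vocalisation: $[0, 0.9)$ s.

Coupling appears as baseline < pre < during, and its development as a
limb-by-age interaction.

## The measurement chain

### Clock synchronisation

Audio and accelerometers run on different clocks. Each session begins with
a five-clap burst by the caregiver; the claps are sharp transients visible
in both streams. `detect_claps()` finds them in the short-time audio
amplitude envelope using an adaptive threshold (median + 8 MAD), and
`estimate_lag()` slides the audio envelope restricted to the clap burst
along the mean caregiver-hand magnitude envelope (both at 60 Hz),
returning the argmax of the normalised cross-correlation with parabolic
(sub-sample) refinement. Restricting the template to the burst keeps
vocalisations and other room sound from diluting the correlation. One
global lag per session is applied (`apply_lag()`); clock drift within a
session is out of scope. On synthetic sessions with injected lags in
$U(-2, 2)$ s the estimator is accurate to well under one sample (1/60 s).

### Preprocessing

Per channel, in this order (the order matters and is fixed):

1. `fill_gaps()` — dropped wireless packets are reinserted on the nominal
   grid and interpolated with a cubic spline (exact on cubic segments);
   interpolated samples stay flagged so no reconstructed data can drive a
   result.
2. `resample_to_rate()` — polyphase resampling to the uniform 60 Hz grid;
   segments recorded at 40 Hz (sensor rate drops) are spline-interpolated
   because polyphase resampling assumes a uniform source grid.
3. `magnitude()` — $Acc(t) = \sqrt{x(t)^2 + y(t)^2 + z(t)^2}$.
4. `highpass()` — 2nd-order Butterworth, 1 Hz cutoff. The gravity
   component is removed by this filter rather than by orientation
   estimation. Filtering is zero-phase (forward–backward) by default so
   that the $\pm 0.9$ s event-locked windows are not shifted by group
   delay; a single-pass option is retained behind a flag. The
   forward–backward amplitude response is the squared magnitude response
   $|H(f)|^2$, which is what the tests check against.

Throw artifacts (the infant flinging a sensor) are masked by
`detect_artifacts()`: samples above a threshold, dilated by a 50 ms guard.
No universal numeric threshold is defensible, so the threshold is exposed
as configuration with a data-driven default (median + 10 MAD of the
magnitude series), mirroring empirical calibration against observed throw
events. Runs longer than 0.6 s are flagged in QC output but remain masked.

### Epoching and the envelope measure

`extract_epochs()` cuts $[-3.5, +5]$ s around each onset (511 samples at
60 Hz, onset at sample 211). Epochs touching the recording edge or any
masked sample are excluded with a reason code. Epochs containing a
following onset are retained by default (`exclude_overlap` flips this;
both behaviours are tested).

Because an accelerometer magnitude trace is oscillatory rather than
centred, baseline correction uses the signal envelopes:
`envelope_baseline_correct()` estimates upper and lower peak-interpolated
envelopes (cubic spline through local extrema, minimum separation 2
samples), and subtracts the mean of their midline over the $[+3.5, +5]$ s
reference span. The reference span is deliberately the epoch tail — that
is how the measure is defined — and is configurable. The correction is
shift-invariant and idempotent.

`analytic_envelope()` then computes the instantaneous amplitude as the
modulus of an approximate analytic signal formed by a 12-tap complex FIR
filter: a least-squares fit of $e^{-i\omega\alpha}$ over the positive
passband (1–12 Hz region at 60 Hz sampling) and 0 over its mirror, with a
small ridge for conditioning. The filter is linear-phase with group delay
$\alpha = 5.5$ samples, compensated by interpolating the envelope back
onto the input grid, so envelope timing is preserved. Against the exact
FFT Hilbert envelope the mid-epoch error on tones in the movement band is
1–3%. Twelve taps is a deliberate constraint of the measure, not a
numerical choice; the full-length FFT Hilbert transform
(`hilbert_envelope_fft()`) is kept as the independent oracle, never as
the implementation.

`window_medians()` takes, per event, limb and window, the median envelope
per side, and averages left and right — one value per vocalisation, limb
and window, the model's unit of analysis. Per-infant aggregation
(`summarise_infant_windows()`) is for description and plots only.
`baseline_diffs()` forms pre−base and during−base differences for the
control models. `locate_inflection()` reproduces, diagnostically, the rule
that fixed the window boundary at ±0.9 s (the strongest curvature change
of the average audio envelope on each side of onset); the analysis windows
themselves stay fixed.

## The models

Event-level rows (median ~ one row per vocalisation × limb × window) feed
four mixed-model families via `lmerTest`:

1. **Global**: `median ~ Time_Window * Time_Point * Limb +
   (1 + Limb | infant)`. Eight candidate structures — four fixed lattices
   from main effects to the full triple interaction, crossed with
   slope/intercept random structures — are compared by AIC/BIC/logLik and
   LRT under ML (`compare_models()`).
2. **Window × time point**: tests the coupling (window) effect and its
   age stability; window contrasts base−pre, base−during, pre−during.
3. **Per-window time point × limb** (baseline, pre, during): the
   developmental crossover, leg−arm per age.
4. **Baseline-corrected differences** (pre−base, during−base) with
   intercept-only random effects (the limb slope is dropped in these
   models).

Estimation is ML wherever likelihoods are compared across structures, and
REML for all reported coefficients, ANOVAs and contrasts — the standard
convention when the source does not state one. Type-II F tests use
Satterthwaite denominator degrees of freedom via `lmerTest`;
`ranova_random()` compares matched-REML fits with and without a random
term (the fixed-effects-only comparator uses the Harville REML
log-likelihood so the scales agree), noting that the boundary null makes
the $\chi^2$ p conservative. Contrasts come from equally weighted
estimated marginal means (`emmeans`) with Bonferroni correction over each
printed block (three window contrasts; four per-age limb contrasts).

Two Cohen's *f* conventions coexist deliberately: omnibus rows use
$f = \sqrt{\mathrm{NumDF}\cdot F/\mathrm{DenDF}}$ (equivalently
$f^2 = \eta^2_p/(1-\eta^2_p)$), which reproduces the published
interaction effect sizes exactly; post-hoc contrast rows use the t-based
$f = |t|/\sqrt{N_{obs}}$ and are labelled as such, because the omnibus
convention does not apply to a single-df contrast and the source
convention for those rows is not stated. `r2_nakagawa()` reports marginal
and conditional $R^2$ with the random variance computed as
$\mathrm{tr}(Z G Z')/n$.

## The synthetic-data generator

`simulate_cohort()` builds complete sessions — WAV, TextGrid,
accelerometer CSVs, YAML manifest — with known ground truth, and
`simulate_rows()` draws the dependent measure directly from the assumed
mixed-model structure when hundreds of cohorts are needed (power, type-I
and coverage studies). Generator defaults are the study conditions:

* sessions of 313 s; vocalisation onsets from a Poisson process at
  6/min (≈31 events/session) thinned by a 0.5 s refractory period (one
  utterance per expiration; no published value, so a physiologically
  modest choice); lognormal durations with mean 0.593 s, sd ≈ 0.5 s;
* window increments +0.21 (pre) and +0.31 (during) m/s², the published
  grand contrast estimates, with per-age leg−arm splits for the baseline
  (0.00, 0.14, −0.39, −0.25 m/s² at 4/6/9/12 months) and for the
  increments taken from the published per-age contrast tables;
* per-infant random intercept sd 0.3, limb-slope sd 0.2 (correlation 0.2,
  unstated in the source, chosen modest positive), residual sd 1.2 m/s²
  (back-computed from the published residual mean square);
* a 0.35 s audio–IMU lag, five claps at 3.0–5.8 s, 13% missing visits
  (matching the reported 41/318 exclusions), and per-channel defect
  probabilities of 0.1 for packet gaps, 60→40 Hz rate drops and ≤0.6 s
  throw artifacts.

The **grand baseline envelope level (1.5 m/s²) is an order-of-magnitude
choice**: no physical-unit baseline is published, so absolute levels in
simulated cohorts are arbitrary while all contrasts and effect sizes are
calibrated.

The movement carrier is band-limited (2–8 Hz) Gaussian noise
amplitude-modulated to the target envelope and normalised so the median
of its exact analytic envelope is 1 — window medians then recover the
injected envelope level without bias. Phase realism is unnecessary
because only envelopes are analysed. A deterministic tone carrier
(`carrier_type = "tone"`) exists for calibration: with noise, gaps and
lag off, the full pipeline recovers injected window medians to under 1%.

What the generator does **not** emulate: acoustically realistic infant
vocalisations (bursts are shaped noise), caregiver speech, room
reverberation, sensor orientation dynamics, or clock drift. Passing tests
therefore demonstrate that the measurement chain and models recover the
assumed structure, not that the assumed structure is the right model of
real infant movement.

## Numerical choices and degenerate inputs

* Onsets snap to the nearest sample; windows are half-open $[a, b)$, so
  base/pre/during contain exactly 96/54/54 samples and the onset sample
  belongs to "during".
* Packet gaps are declared when consecutive timestamps differ by more
  than 1.5× the nominal interval; boundary gaps are trimmed (they cannot
  be interpolated) with a warning.
* A constant epoch has upper = lower = signal, so baseline correction
  maps it to exactly zero; fewer than two interior extrema falls back to
  the signal itself.
* Events whose left or right channel epoch is excluded contribute the
  available side and are flagged (`n_sides = 1`).
* Mixed-model non-convergence and singular fits are flagged in the
  `fit_result`, never silently dropped; per-session pipeline failures are
  isolated and summarised in the run manifest.

## Problem sizes used in the test suite

Simulation-based checks run at desk scale, chosen as the smallest sizes
at which the targeted property is comfortably identified: lag recovery
over 50 sessions of 40 s; effect-recovery cohorts of 60 infants × 4
visits × 40 events (a dozen replicates); Wald-CI coverage at 200
replicates of 60 infants × 4 events/visit; type-I control at 200
zero-coupling cohorts of 16 infants × 6 events/visit. The acceptance
script (`scripts/acceptance.R`) re-runs the same computations from
scratch with a caller-supplied seed.

## Known limitations

* Single global lag per session; no clock-drift correction.
* The artifact threshold default is data-driven, not physically
  calibrated; supply a measured threshold where one exists.
* The 12-tap analytic envelope under-tracks carriers below ~2 Hz; the
  movement band of interest (2–8 Hz) is covered to a few percent.
* Published headline coefficients depend on embargoed recordings and are
  not reproducible here; the package instead verifies the arithmetic
  printed in the source tables and its own recovery of injected effects.
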