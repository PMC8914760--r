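---
title: "Cuffless blood-pressure estimation from PPG morphology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cuffless blood-pressure estimation from PPG morphology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgbp)
```

## The estimation problem

A wrist-worn photoplethysmography (PPG) sensor measures blood-volume
changes in tissue optically.  The pulsatile (AC) component of the signal
tracks each arterial pulse, and the shape of that pulse carries
information about arterial pressure: stiffer, higher-pressure systems
produce steeper upstrokes and a different balance between the systolic
ejection phase and the diastolic runoff.  `ppgbp` implements a complete
software pipeline that turns a raw single-channel PPG record plus a
subject's age and gender into estimates of systolic (SBP) and diastolic
(DBP) blood pressure, together with the validation statistics used to
judge cuffless BP devices.

The pipeline has five stages:

1. **Preprocessing** — zero-phase 0.5–10 Hz band-pass filtering, beat
   delineation, and optional rejection of 15-s windows whose activity
   count exceeds a threshold (steady-state gating).
2. **Feature extraction** — eight morphology parameters per pulse,
   averaged over 15-s windows: the systolic and diastolic areas relative
   to the total area and to the pulse amplitude, the maximal upslope, the
   systolic and diastolic durations, and the mean beat-to-beat (RR)
   interval.  Age and gender complete a ten-input feature vector.
3. **Regression** — Gaussian process regression (GPR) with an
   exponential kernel, fitted per (gender, age-group) cell.
4. **Feedback calibration** — a single reference cuff reading is used to
   select, among all age-group models of the subject's gender, the one
   that predicts the reference best; the calibration pair can then be
   absorbed into that model as a personal model.
5. **Evaluation** — error summaries on `delta = actual − estimated`,
   AAMI bound, BHS letter grades, Bland–Altman limits of agreement,
   Pearson correlation, Shapiro–Wilk normality, subgroup breakdown by
   hypotension/normotension/hypertension, and a sweep over age-grouping
   widths.

## The regression model

Given training pairs $\{x_i, y_i\}_{i=1}^n$ (standardized feature
vectors and BP targets in mmHg), the model is a zero-mean Gaussian
process with observation noise:
$y_i = f(x_i) + \varepsilon_i$, $\varepsilon_i \sim N(0, \sigma_n^2)$,
so that $y \sim N(0, K + \sigma_n^2 I)$.  The covariance is the
exponential kernel

$$k(x_i, x_j) = \sigma_f^2 \exp\left\{-\frac{(x_i-x_j)^\top(x_i-x_j)}{\sigma_l}\right\},$$

parameterized through $\theta_1 = \log \sigma_l$ and
$\theta_2 = \log \sigma_f$.  Predictions at a query $x_*$ are the usual
GP posterior mean and variance,
$\bar f(x_*) = k_*^\top (K + \sigma_n^2 I)^{-1} y$ and
$V(x_*) = k(x_*, x_*) - k_*^\top (K + \sigma_n^2 I)^{-1} k_*$.

Two points deserve comment.

* **Distance form.**  As written above, the kernel decays with the
  *squared* Euclidean distance over $\sigma_l$.  The name "exponential
  kernel" conventionally refers to decay with the unsquared distance
  $\lVert x_i - x_j\rVert / \sigma_l$.  The squared form is the default
  here; `kernel_params(..., distance = "euclidean")` selects the
  conventional form.  Both are supported behind the same interface, and
  an automatic-relevance-determination variant (one length scale per
  feature, `ard = TRUE`) is available as well; the single-length-scale
  squared form is the default because that is the form of the printed
  covariance above.
* **Fitting.**  Hyperparameters $(\theta_1, \theta_2, \log\sigma_n^2)$
  maximize the log marginal likelihood
  $-\tfrac12 y^\top (K+\sigma_n^2I)^{-1} y - \tfrac12 \log|K+\sigma_n^2I|
  - \tfrac n2 \log 2\pi$
  by L-BFGS-B with analytic gradients from five fixed starting points,
  with box bounds $[-5, 5]$ on the log scales and $[-8, 3]$ on the log
  noise variance.  Cholesky factorization with escalating jitter
  ($10^{-10}\,\mathrm{tr}(K)/n$ up to $10^{-4}$) guards against
  near-singular kernels.  Inputs and targets are z-scored on the
  training split only.  Because the starting points are fixed, fitting
  is deterministic, and permuting the training rows changes predictions
  only at numerical-noise level.

## Age-group model banks and feedback calibration

BP distributions widen and drift with age, and pooling all ages makes
the target distribution markedly non-normal.  Models are therefore
trained per (gender, age-group) cell: SBP uses 30-year groups
(<30, 30–60, ≥60) and DBP 15-year groups (<30, 30–45, 45–60, 60–75,
≥75) — with both genders populated that is 6 SBP and 10 DBP models.
Bins are half-open and lower-inclusive; cells with fewer than 5 distinct
subjects are skipped (not merged) and recorded in the bank's provenance.

Uncalibrated prediction simply uses the subject's own demographic cell.
Feedback calibration treats the subject's chronological age group as
uncertain: every age-group model of the subject's actual gender predicts
the calibration feature vector(s), each group is scored by mean absolute
error against the reference cuff reading(s), and the minimal-error group
becomes the subject's personal model.  Ties break toward the
chronological bin, then toward the younger bin.  The calibration pairs
can then be absorbed into the personal model's training set with
hyperparameters frozen (`augment_model()`), which anchors the model at
the subject's operating point; the bank itself is never modified.  One
reference reading is the default — it matches the single cuff
measurement a user takes during device setup — but the interface accepts
several and averages their errors.  Reference readings are absorbed as
training observations, never used as runtime input features, which would
make the estimator circular.

## The synthetic cohort generator

The clinical database the method was developed on is available only on
request, so the package ships a generator that emulates its documented
properties and provides exact ground truth.  The generator is a
first-class, tested module; its defaults define the study conditions
used throughout the tests.

**Demographics and BP.**  Ages 15–94 with a young-adult mode (35% of
subjects uniform on 20–34, the rest uniform on 15–94, mirroring a
community cohort dominated by 25–29-year-olds).  SBP is a normotensive
base $105 + 0.45(\text{age}-15)$ mmHg (SD 12) plus, for an
age-increasing hypertensive fraction ($0.06 + 0.005(\text{age}-30)$,
capped at 0.40), a right-skewed Gamma(2, 16) elevation.  DBP rises to a
peak near age 60 and declines after ($65 + 0.25(\text{age}-15)$ up to
60, then $-0.20$/year).  Gender adds +4/+2 mmHg (male) to SBP/DBP.
Readings are clamped to the clinically screened ranges 80–250 /
40–150 mmHg with SBP > DBP enforced.  These choices reproduce the
documented validation-population requirements — at least 5% of readings
at SBP ≤ 100 and at least 5% at SBP ≥ 160 mmHg — with margin at cohort
sizes of a few hundred.

**Waveforms.**  Each beat is the sum of a systolic and a diastolic
Gaussian.  The morphology link ties the shape to the subject:

| parameter | default link | effect |
|---|---|---|
| systolic width `ws` | $0.10 + 0.009\,r(\text{age}) + 10^{-4}(\text{age}-50) - 3.2\times10^{-4}(\text{SBP}-120)$ s | steeper upslope and larger systolic-area fraction at higher SBP |
| diastolic amplitude `ad` | $0.45 + 0.05\,q(\text{age}) + 5\times10^{-4}(\text{age}-50) + 0.005(\text{DBP}-75) - 0.002(\text{SBP}-120)$ | larger diastolic-area fraction at higher DBP |
| systolic delay `ts` | $0.18\sqrt{RR}$ s | |
| diastolic spacing `dtd` | $(0.30 - 8\times10^{-4}(\text{age}-50))\sqrt{RR}$ s | |
| diastolic width `wd` | $0.22\sqrt{RR}$ s | |

$r(\text{age})$ and $q(\text{age})$ are *vascular regime levels*: step
functions over the 30-year (SBP) and 15-year (DBP) age groups.  They
encode the design assumption that arterial aging shifts the mapping
from BP to pulse shape between age groups rather than smoothly within
them.  This is what makes the feedback-calibration search identifiable:
if the BP-to-shape mapping were one global smooth function, every
age-group model would learn the same inverse mapping and the reference
reading could not distinguish groups.  The $\sqrt{RR}$ scaling keeps
beats from fusing at high heart rates and from leaving a flat,
foot-ambiguous gap at low ones.  White noise (SD 0.02 of the unit pulse
amplitude) and sinusoidal baseline wander (amplitude 0.1, frequency
drawn below 0.4 Hz) are added on top; activity counts are zero,
emulating the at-rest measurement protocol.

**What the generator does not emulate.**  Optical skin physics, LED
wavelength effects, motion-artifact waveforms, dicrotic-notch morphology,
arrhythmia, and beat-to-beat heart-rate variability.  Pulse shape is a
deterministic function of (SBP, DBP, age, HR) plus additive noise, so
the synthetic mapping is cleaner than wrist PPG in the field.  Passing
tests on this cohort demonstrate the *pipeline's* correctness — that
the estimator recovers BP whenever the morphology carries it — not
clinical accuracy on real skin.

**Ground-truth oracle.**  `ground_truth_features()` computes each
subject's ideal feature vector by dense numerical analysis of the
noise-free periodic pulse (2048 Hz grid, analytic derivative for the
maximal slope, trapezoid areas against the onset-to-end chord).  The
extractor — which works on the 256 Hz sampled waveform with
first-difference slopes — is required to agree within 2% on noise-free
input; this is tested over 100 random profiles.

## Numerical and design choices

* **Pulse delineation.**  Systolic peaks are found on a 25-ms smoothed
  copy with a minimum spacing of 70% of the dominant beat period
  (estimated from the periodogram over 0.5–3.2 Hz, with a subharmonic
  check so a prominent diastolic wave is not double-counted), floored at
  0.33 s (180 bpm).  Pulse feet are the minima between consecutive
  peaks; edge beats whose foot search would be clipped by the record
  boundary are dropped rather than emitted truncated.
* **Systolic/diastolic split.**  The split point is the systolic *peak*,
  not the dicrotic notch: notch detection is unreliable on wrist PPG and
  the two-Gaussian pulse model has no stable notch.
* **Area baseline.**  Areas are measured against the straight chord from
  onset to end amplitude, which detrends residual wander within a beat.
  Areas carry units of a.u.·s, so A1/AC and A2/AC are in seconds.
* **Filter realization.**  4th-order Butterworth applied
  forward-backward; the −3 dB corners sit at 0.8×low and 1.15×high so
  the nominal 0.5–10 Hz band lies in the flat part of the response.
  Records are odd-reflection padded before filtering to absorb the
  multi-second start-up transient of the 0.4 Hz corner.
* **Windows.**  15-s analysis windows; pulses are assigned by
  systolic-peak time; windows with fewer than 3 valid pulses are
  dropped, as are partial trailing windows.  Activity gating is
  boundary-inclusive (a count equal to the threshold is accepted).
* **Grading conventions.**  Cumulative error percentages use inclusive
  thresholds (|delta| ≤ 5 counts toward the 5-mmHg column), the AAMI
  comparison is inclusive (|mean| ≤ 5 and SD ≤ 8 mmHg), the sample
  (n−1) standard deviation is used throughout, and the overall BHS
  grade is the worst of the three per-threshold grades.  The
  ±1.96 SD lines are limits of agreement in the Bland–Altman sense.
* **Gender encoding.**  0 = female, 1 = male.
* **Age-grouping sweep.**  Group widths are anchored at age 30 with a
  catch-all bin below 30 and an unbounded top bin, which reproduces both
  default schemes; width 100 means a single bin (no grouping).

## Problem sizes

The reference experiment — also what `scripts/acceptance.R` runs —
draws 435 subjects, splits 306/129 into training and test by seeded
permutation, trains the SBP bank on all training windows (four 15-s
windows per 60-s record), calibrates each test subject with their first
window against one cuff reading, and evaluates the remaining three
windows per subject (387 pairs).  This runs in under a minute on one
CPU.  Unit tests use smaller cohorts (tens to a couple of hundred
subjects) chosen to exercise every code path while keeping the suite
fast; the Shapiro–Wilk grouping property is averaged over 20 seeds of
200 subjects, and hyperparameter recovery over 20 seeded draws of 100
points.

## Known limitations

* The generator's BP-to-morphology link is a modeling stand-in, not a
  claim about physiology; coefficients were chosen for monotonicity,
  invertibility and desk-checkability.
* Calibration quality rests on within-subject feature stability: the
  synthetic records are stationary, so one calibration window transfers
  almost perfectly to the rest of the record.  Real long-term drift
  (posture, temperature, vascular tone) is not modeled, and the package
  provides no drift-triggered re-calibration scheduling.
* With a single reference reading, age-group selection can in principle
  tie; ties break toward the chronological group.
* No sparse approximations: per-cell cohorts of a few hundred windows
  are dense-solve territory.
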