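---
title: "Measurement models and numerical choices in cardioqt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement models and numerical choices in cardioqt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioqt)
```

cardioqt implements the measurement chain of a cardiac-electrophysiology
study of left ventricular non-compaction: ECG interval delineation with
heart-rate-corrected QT, beat-to-beat QT-variability statistics, whole-cell
voltage-clamp curve analysis, action-potential metrics, and area-fraction
histology. This vignette records the models, the parameters that matter,
and the numerical decisions — especially where the underlying measurement
conventions leave genuine freedom.

## ECG delineation

A single-lead record (mV, fixed sampling rate) is first high-pass filtered
at 0.5 Hz with a 2nd-order Butterworth applied forward and backward
(`signal::filtfilt`), i.e. a zero-phase, effectively 4th-order response.
Intervals are then defined by threshold rules:

* **PR** — from P-wave onset to the R peak. "Onset" is operationalized as
  the point, scanning back from the P peak, where the deflection has fallen
  to 10 % of its height above the isoelectric line, linearly interpolated
  between samples.
* **QRS** — from Q onset (same 10 %-of-trough rule at the Q wave) to the
  point where the S wave recrosses the isoelectric line.
* **QT** — from Q onset to the point where the T wave has completed 90 % of
  its decline, i.e. has fallen to 10 % of the T-peak height above baseline.

The isoelectric level is not part of the printed rules, so we define it:
the median of a 10-ms window ending 5 ms before the P onset, found in two
passes (a coarse onset locates the window, the refined level re-derives the
onset). For the T-wave rules a second, T-local baseline is estimated from
the quiet segment after the T search window. This matters because a
high-pass filter at 0.5 Hz makes the baseline droop *within* a beat
whenever the beat rate is near the cutoff: at a human heart rate (~1.1 Hz)
the inter-beat baseline sits several hundredths of a mV below the pre-P
level, and a single per-beat baseline would bias the 10 % T threshold.
Murine rates (5–12 Hz) are far above the cutoff and unaffected. We also
evaluated lower cutoffs for human records: below ~0.25 Hz respiratory-band
wander (0.2 Hz in the generator) passes essentially unattenuated and
delineation collapses, so 0.5 Hz with a T-local baseline is the better
operating point under these conditions.

Two robustness devices guard the threshold rules against sampling noise,
both configurable through `delineation_windows()`:

* landmark detection runs on moving-average-smoothed copies of the signal —
  a wider window for the low-amplitude P and T waves (1.5 ms mouse, 14 ms
  human) and a much lighter one for the narrow, high-amplitude QRS
  (0.5 / 2 ms) so its deflections are not widened;
* threshold crossings on shallow slopes are *debounced*: a crossing counts
  only if it persists for twice the smoothing width, which removes the
  systematic early-crossing bias that first-crossing rules suffer on noisy
  shallow declines (most visible at the human T end).

Search windows scale with species (P search 50 / 300 ms before R, QRS
half-width 15 / 60 ms, refractory 50 / 250 ms for mouse / human); all are
configurable. R peaks are detected by an amplitude threshold at half the
maximum with greedy acceptance by height under the refractory window; the
published workflow measured offline in commercial software, so this
detector is plumbing, not a reproduced method.

Intervals are reported as arithmetic means over all delineable beats, with
the per-interval beat count (`n_beats_averaged`) recorded rather than
enforcing any fixed number; the reference workflow averaged on the order of
450 beats per animal and the mouse generator default matches that.

### QT correction

Three conventions, each an identity at its reference rate and strictly
increasing in QT:

* Bazett (human): `QTc = QT / sqrt(RR)` with RR in seconds **derived from
  heart rate** (`RR = 60/HR`). Integer reporting truncates toward zero.
* Hodges: `QTc = QT + 1.75 (HR − 60)`; integer reporting rounds half up.
* Murine normalization: `QTc = QT / sqrt(RR/100)`, RR in ms — the mouse
  analogue of Bazett anchored at RR = 100 ms.

The HR-derived RR and the two integer-reporting modes are what make the
packaged patient table reproduce exactly, subject by subject; the printed
RR column is internally inconsistent with the printed QTc for several
subjects, so it is stored but not used for recomputation. Full precision is
always retained alongside the reported integer.

## QT variability

On an ordered QT series (ms) with aligned HR (bpm):

$$\mathrm{QTvar} = \tfrac{1}{n-1}\sum_i (QT_i - \overline{QT})^2,\qquad
\mathrm{SDqt} = \sqrt{\mathrm{QTvar}},$$
$$\mathrm{STVqt} = \frac{\sum_i |QT_{i+1}-QT_i|}{n_d\sqrt{2}},\qquad
\mathrm{QTVN} = \frac{\mathrm{QTvar}}{\overline{QT}^2},$$
$$\mathrm{QTVI} = \log_{10}
  \frac{\mathrm{QTvar}/\overline{QT}^2}{\mathrm{HRvar}/\overline{HR}^2},
  \qquad
\mathrm{RMSSDqt} = \sqrt{\tfrac{1}{n-1}\sum_{i=1}^{n-1}(QT_{i+1}-QT_i)^2}.$$

Two printed-formula ambiguities are resolved on the side of computability
and the markers' universal definitions: the STV summation can only run over
the $n-1$ existing successive differences (a conventional fixed
$n_d = 30$ denominator is available as a mode), and RMSSD carries its
square root. Means are taken from the analyzed series themselves, with
overrides for fixture replication. A constant QT series makes QTVI
degenerate; the panel flags it and reports $-\infty$ rather than failing.

## Voltage-clamp analysis

Amplitude conventions: the transient amplitude is the extremum within the
pulse minus the mean current over the last 5 % of the pulse
("peak minus end"); the sustained amplitude is that end level minus the
pre-pulse baseline. The first 0.3 ms of each pulse is blanked from peak
searches (capacitive transient); both the 5 % end window and the blanking
are configurable, since the underlying conventions say only "at the end of
the pulses". Densities divide by cell capacitance.

The density–voltage relationship is fitted with
$$I(V) = (V - E_{rev})\, G_{max}\, \bigl(1 + e^{-(V - V_h)/k}\bigr)^{-1},$$
the sign convention chosen so occupancy rises with depolarization and the
slope factor $k$ is reported positive (the falling sign is used for
availability curves). Initialization: $E_{rev}$ from the linear
extrapolation of the fully activated limb, $V_h$ from the half-maximal
conductance crossing, $k$ from the 10–90 % rise span divided by 4.4,
$G_{max}$ from the maximal chord conductance; `minpack.lm::nlsLM` does the
optimization with $V_h$ bounded ±50 mV around its start. Chord conductance
$G = I/(V - E_{rev})$ excludes points within 1 mV of $E_{rev}$ before
normalization. On noiseless model data the conductance route and the
direct I–V fit agree to within 1 mV / 0.5 mV in $V_h$ / $k$ — two routes,
one truth — and this is enforced by test.

Decay kinetics are fitted from the peak to the pulse end as
$A e^{-t/\tau} + C$ or $A_f e^{-t/\tau_f} + A_s e^{-t/\tau_s} + C$ with
$\tau_f < \tau_s$ imposed by ordering after the fit (not by constrained
optimization). A biexponential fit whose minor component carries under 2 %
of the amplitude falls back to the monoexponential, flagged; a flat trace
is flagged degenerate with $\tau$ = NA. For fast Na⁺ current the
activation time constant (~0.5 ms) overlaps the fast inactivation constant
(~1.3 ms), and a plain fit from the peak inflates both decay constants by
tens of percent; when the activation constant is known (as it is for model
data, and as it is routinely estimated in practice), `decay_kinetics` can
divide the trace by $1 - e^{-t/\tau_{act}}$ before fitting, restricted to
where activation exceeds 0.5. With the correction the noiseless recovery
is exact.

Recovery from inactivation fits the P2/P1 peak ratio against the coupling
interval with $1 - e^{-t/\tau}$; the plateau is fixed at 1 by default
(an optional free plateau accommodates incomplete recovery). The late
(persistent) current is the mean over the last 10 % of a 500-ms pulse as a
percentage of the baseline-subtracted peak. Charge density integrates the
current above its end-of-pulse level from the peak to the pulse end
(trapezoidal rule, reported in pC/pF), so a purely sustained current
carries zero charge by definition. The inward rectifier is measured at the
end of its 250-ms steps. No liquid-junction-potential correction is
applied anywhere, matching the recording convention the package mirrors.

Action potentials: RMP is the mean pre-stimulus voltage, APA the peak above
RMP, and APD$_x$ the time from the peak until the voltage first falls below
peak − $x\%$·APA, linearly interpolated. Whether APD is referenced to the
peak or the upstroke is not fixed by convention; the peak is the default
with an `upstroke` option (midpoint crossing). Deflections under 10 mV are
refused as "no AP".

## Histology area fractions

The metrics consume co-registered *binary* masks, so their arithmetic is
exactly testable; interactive thresholding of raw fluorescence is upstream
of the contract (a plain Otsu helper is included for convenience only).

* Cx43–ICD co-localization: $100 \cdot |cx43 \cap ncadh| / |ncadh|$.
* Lateralization: $100 \cdot |cx43 \cap lateral| / |cx43 \cap ncadh|$ with
  $lateral = wga \setminus ncadh$, so no pixel is counted on both sides of
  the ratio (whether the original workflow excluded WGA-positive ICD pixels
  is unstated; the subtraction is our choice and is recorded here).
* Fibrosis: $100 \cdot |psr \cap tissue| / |tissue|$.

Per-animal values average three sections, the conventional sampling.

## Synthetic generators

The generators define the conditions under which the package's accuracy
claims are made; each returns machine-readable truth alongside its data and
is bit-reproducible from its seed (single RNG stream per generator, default
seed 20250507).

**ECG.** Each beat is a sum of Gaussian bumps (P, Q, R, S, T plus a small
positive J bump after S — without it a lone Gaussian S wave never recrosses
the baseline and the QRS-end rule would be noise-defined). Bump placement
is *solved* (1-D root finding) so that the programmed PR, QRS and QT are
exact under the package's own measurement rules applied to the noiseless
template; per-beat QT jitter shifts the T complex. Mouse defaults: HR 500
bpm, PR 40 ms, QRS 10 ms, QT 45 ms, R 1.0 mV, T 0.25 mV, QT jitter 1 ms,
white noise 0.01 mV, 0.2 Hz / 0.2 mV wander, 450 beats at 2 kHz — an
anesthetized-adult-mouse regime sized to the ~450-measurement averaging
convention. Human defaults: HR 65, PR 160, QRS 90, QT 400 ms, 60 beats at
500 Hz. What the generator does *not* emulate: biphasic or inverted T
waves, ectopy, motion artefacts, and rate-dependent morphology change; a
passing round trip shows the rules are implemented correctly, not that
they are robust to every clinical waveform.

**QT/HR series.** Stationary AR(1) with programmed mean, SD and lag-1
correlation — the simplest process that exercises both the variance-based
and the successive-difference markers, including the white-noise identity
$E[\mathrm{RMSSD}] \to \sigma\sqrt{2}$.

**Voltage clamp.** A separable gating model
$I(t) = G_{max}\, m_\infty(V)\,(1-e^{-t/\tau_{act}})\, h(t)\,(V-E_{rev})$
with Boltzmann $m_\infty$, biexponential $h$ decaying to a plateau solved
so that the end-of-pulse/peak ratio equals the programmed late fraction,
Boltzmann steady-state availability for conditioning prepulses, and
monoexponential recovery for P1/P2 protocols. Default parameters are
realistic wild-type mouse ventricular values (fast Na⁺: $V_{h,act}$ −52.9
mV, $k$ 4.0; $V_{h,inact}$ −86.9 mV, $k$ 5.0; $\tau_f/\tau_s$ 1.3/4.5 ms;
$\tau_{react}$ 8.2 ms; analogous presets for L-type Ca²⁺ and outward K⁺).
Because the model is separable, the peak density curve is exactly
Boltzmann-scaled-ohmic, which is what makes noiseless parameter recovery a
sharp oracle test. Multiplicative (2 %) and additive noise are available;
with 2 % noise the median recovery error over 100 replicates stays under
5 % for every parameter (enforced by test, runtime ~10 s).

**Action potentials.** A 1-ms linear upstroke and a monotone Hyman-filtered
cubic repolarization anchored exactly at the programmed APD20/50/90
voltages, then an exponential settle — programmed APDs are exact by
construction.

**Masks.** Rod-shaped cells in a brick layout; ICD bands at cell ends,
lateral strips along the sides; Cx43, PSR pixels allocated by exact
counting (sampling without replacement), so the achieved fractions equal
the programmed ones up to integer rounding.

## Problem sizes and accuracy statements

The test suite's simulation sizes are chosen to make each claim sharp at
modest cost: 60-beat records for per-seed ECG round trips and the full
450-beat default in the end-to-end check (mouse round-trip error < 2 ms on
every interval); 10⁵-beat series for the √2 white-noise limit (2 %) and SD
calibration; 100 replicates for noisy gating recovery; 256² masks. Human
delineation is verified at 3 ms: with a 0.5 Hz high-pass, human baseline
droop bounds what threshold rules can do (see above), and the murine
pipeline is the raw-ECG use case the package reproduces.

## Known limitations

* The delineator assumes upright R and T deflections in a single lead;
  inverted or biphasic morphologies need window/polarity overrides.
* Threshold-rule accuracy for human records is limited by the 0.5 Hz
  high-pass distortion, not by noise; a cubic-spline baseline model would
  be the next step if sub-millisecond human accuracy were needed.
* The gating model omits series-resistance and leak artefacts, Markov-state
  kinetics and temperature effects; parameter recovery under those
  distortions is untested by design.
* The variability fixture's printed QTVN/QTVI columns cannot be reproduced
  from the per-subject summary values alone (they require the unpublished
  beat series); they are stored verbatim and only the SDqt–QTvar
  consistency is asserted.
* Mask metrics assume perfect co-registration; no registration or stain
  unmixing is attempted.
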