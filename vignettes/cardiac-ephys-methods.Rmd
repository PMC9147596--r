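---
title: "Methods: murine cardiac electrophysiology feature extraction"
author: "cardioephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: murine cardiac electrophysiology feature extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioephys)
```

`cardioephys` implements, as one tested pipeline, the quantitative
procedures used to characterise delayed ventricular repolarization in a
murine model of Rett syndrome (Mecp2-null males versus wild-type
littermates): surface-ECG interval metrics with two QT rate corrections,
ventricular action-potential (AP) feature extraction including beat-to-beat
variability of repolarization, fast sodium-current (I~Na~) kinetics from
voltage-clamp sweep families, late sodium-current (I~Na,Late~)
quantification with drug percent-inhibition arithmetic, and respiratory
apnoea scoring from plethysmography breath events. Because no raw
recordings are publicly deposited for this kind of study, the package
carries a first-class synthetic-data generator that emulates every input
the analysis stages consume, with known ground truth.

Canonical units throughout: time in ms, potential in mV, current in pA,
capacitance in pF, current density in pA/pF, charge density in pC/pF.
Inward current is negative; figures and group summaries that quote
"magnitudes" state so explicitly. The default sampling interval is 0.1 ms
(a 10 kHz digitization rate).

## ECG intervals and QT rate correction

Per-complex intervals come from fiducial annotations (QRS onset, R peak,
QRS end, QT end): `RR(i)` is the spacing of successive R peaks, heart rate
is `60000/RR`, `QRS = qrs_end - qrs_on`, and `QT = qt_end - qrs_on`. QT end
is taken from the annotations rather than delineated automatically — "the
time point after the T-wave peak" is not an operational definition, and the
upstream measurements were made on manually placed fiducials.

Murine QT intervals are rate corrected two ways, with RR in milliseconds:

$$\mathrm{QTc_1} = \frac{QT}{\sqrt{RR/100}}, \qquad
  \mathrm{QTc_2} = QT + 0.3173\,(170 - RR).$$

Taking RR in ms is the only reading under which the linear correction
reproduces the published wild-type value (51.9 ms at RR 130.7 ms gives
64.37 ms against a printed 64.4): for murine RR near 130 ms the correction
term is positive, as required by QTc exceeding QT.

`summarise_ecg()` averages the first run of five consecutive clean
complexes — complexes overlapping declared (or detected) breathing-noise
intervals are skipped — and computes QTc per complex before averaging. On
physiological RR jitter (coefficient of variation 5%) the convexity gap
between "mean of per-complex QTc" and "QTc of the means" stays below
0.2 ms for the square-root correction and is identically zero for the
linear one; the package reports the per-complex average.

The bundled R-peak detector thresholds the rectified signal at a
configurable fraction (default 0.6) of its 98th percentile with a 30 ms
refractory period. It exists because the fiducial-based workflow needs
R-peak times when only a raw trace is available; it is deliberately simple
and is validated against the generator's ground-truth beat times.

## Action-potential parameters and BVR

For each beat: resting membrane potential (RMP) is the mean over the 10 ms
window ending at the stimulus onset; overshoot is the maximum potential;
amplitude is overshoot minus RMP; maximum upstroke velocity is the largest
central-difference dV/dt after a 3-point moving average (mV/ms, i.e. V/s).
APD~x~ is measured from the instant of maximum dV/dt — which removes
stimulus-latency jitter, on which the source methods are silent — to the
first downward crossing of `overshoot - x/100 * amplitude`, linearly
interpolated between samples. Triangulation is APD~90~ − APD~25~.

Beat-to-beat variability of repolarization over 10–15 consecutive APs:

$$\mathrm{BVR} = \frac{\sum |APD_{90}(n+1) - APD_{90}(n)|}{D\sqrt{2}},$$

where `D` is taken as the number of difference terms (one fewer than the
number of beats). The defining formula's "n beats" is ambiguous; the
N−1 denominator makes BVR coincide with the classic Poincaré short-term
variability for alternating series and is the default, with the plain-N
variant selectable via `ephys_config(bvr_denominator = "n")`.

## Fast sodium current

The fast-I~Na~ chain is: peak I–V (`peak_iv`), reversal potential from the
ascending limb (`estimate_erev`), chord conductance `G = I/(V - E_rev)`
(`conductance`), Boltzmann activation fit on `G/G_max` over −80…−20 mV
(`fit_activation`), availability fit on `I/I_max` over −150…−50 mV
(`fit_availability`), single-exponential inactivation time constants
(`fit_inactivation_tau`), the steady-state window current
(`window_current`), and biexponential recovery from inactivation
(`fit_recovery`):

$$\frac{G}{G_{max}} = \frac{1}{1 + e^{(V_{0.5}-V_m)/k}}, \qquad
  \frac{I}{I_{max}} = 1 - \frac{1}{1 + e^{(V_{0.5}-V_m)/k}},$$

$$\frac{P_2}{P_1}(t) = 1 - \left(A_f e^{-t/\tau_{fast}} +
  A_s e^{-t/\tau_{slow}}\right).$$

Numerical choices:

* All fits are unweighted nonlinear least squares (Levenberg–Marquardt via
  `minpack.lm`), parameter tolerance 1e-10. Starting values are derived
  from the data: the Boltzmann midpoint from the interpolated half-maximum
  crossing and slope from the quartile levels divided by 2.2 (twice
  `log(3)`); exponential time constants from log-linear regression on the
  early and late decades. When the tight tolerance drives an amplitude to
  its zero bound the fit is retried at the solver's default tolerance, and
  a recovery fit whose fast amplitude vanishes is relabelled as a
  single-component fit with a warning.
* `G_max` and `I_max` are the maxima *observed during the protocol*, never
  fitted parameters.
* The recovery time constants are fitted on a log scale with
  `tau_slow = tau_fast + exp(increment)`, which enforces positivity and
  the fast/slow ordering structurally.
* The ascending limb for the reversal-potential extrapolation is every I–V
  point positive to the voltage of peak (most negative) current, with at
  least three required; conductance points within 1 mV of `E_rev` are
  excluded because the chord quotient degenerates there.
* The inactivation-decay fit runs from 0.2 ms after the current peak to
  the time the magnitude reaches 5% of the peak (capped at the step end);
  both bounds are config keys because the upstream fit window is unstated.
* The window current is evaluated on a −120…+20 mV grid in 2 mV steps as
  activation × availability × `G_max` × driving force; the inward
  (negative) sign is removed for display, as conventional for window
  plots. Absolute window magnitudes are not reproducible without the
  per-strain `G_max` values, which are unpublished; the package therefore
  tests the curve's shape properties (closed tails, peak located between
  the two midpoints, linearity in `G_max`) against a dense-grid search.

### Peak measurement under noise

The default peak measure is *isochronal*: the peak instant is located once
on the sweep with the largest boxcar-smoothed (1 ms) excursion, and every
sweep is then read there, as the mean over a 0.5 ms window trailing the
peak instant. A per-sweep extremum search (available as
`ephys_config(peak_measure = "search")`) is the textbook definition but is
an extreme-value statistic: on sweeps carrying little or no current it
returns the largest noise excursion in the window, which puts a strictly
positive floor under the tail of the I–V relation and visibly biases the
fitted Boltzmann slope. Because the fast-current peak latency is
essentially voltage independent, the isochronal read is unbiased on null
sweeps; simulation at 2%-of-peak noise shows the mean recovery error of
all five kinetic parameters staying well inside the published group SEMs.
Peak magnitudes for normalised curves are oriented by the sign of the
largest sweep rather than folded through `abs()`, so zero-current reads
stay symmetrically distributed.

## Late sodium current

I~Na,Late~ is isolated as the sodium-sensitive current by subtracting the
trace recorded after equimolar NMDG replacement of external Na⁺ from the
control trace, and quantified by three measures that all exclude the large
initial transient: density at 300 ms and at 600 ms into the 1 s step, and
the trapezoidal current integral between 350 and 800 ms in pC/pF. Whether
the original 300/600 ms reads were point samples or short means is
unstated; the package defaults to a ±5 ms windowed mean for noise
robustness (`late_window_ms = 0` gives point reads). All three measures
are linear in the trace, which the tests exploit. Drug effects are
reported as percent inhibition on magnitudes,
`100 (1 - |post|/|pre|)`, per measure.

## Apnoea detection

Breath-event input is a table of onset and expiration times (Te); raw
plethysmography flow segmentation is out of scope. The rule: a running
average of Te is taken every minute, and a breath whose Te exceeds 4× the
average in force is an apnoea. The wording leaves the windowing open; the
default interpretation is a per-minute reference — the mean Te of the
preceding 60 s applies to all breaths of the following minute — with a
per-breath trailing 60 s mean selectable
(`ephys_config(apnoea_reference = "trailing")`). Two further decisions:
apnoeic breaths are excluded from later reference windows, so a long
apnoea cannot inflate the baseline and mask its successors; and
consecutive apnoeic breaths merge into one episode whose length is their
summed Te ("duration of each episode" is episode-level). The first 20 min
of a recording is an adaptation period; only episodes starting in the
subsequent 20 min analysis window are scored. The detector is tested for
exact agreement with an independently written brute-force implementation
of the same rule on 1000 randomised breath series, for monotonicity in the
threshold factor, and for invariance under rescaling all Te (the rule is
ratio based).

Across-animal association between mean APD~90~ and mean apnoea length is
summarised by the Pearson correlation with the usual t-transform p-value;
at the published effect size (r = −0.07, n = 11) this reproduces the
reported p of 0.84.

## Group statistics

The analysis unit is the cell, matching the upstream reporting; animal
identifiers are carried through `group_report()` so summaries can state
"n cells from m mice", but no mixed-effects modelling is layered on top.
Two-sample comparisons use Student's or Welch's t-test; in `"auto"` mode
an F-test of variance equality at 0.05 selects between them — the upstream
criterion for "equal or unequal variances as appropriate" is unstated, so
the rule is documented here as a package decision. Degenerate inputs
(zero-variance groups, identical pairs) return the limiting statistic and
p-value with a warning instead of erroring. Multi-group ANOVA machinery is
deliberately out of scope; only the two-sample, paired, and correlation
procedures the pipeline needs are exposed.

## The synthetic-data generator

The generator exists to give every analysis stage an input with known
ground truth, at the study's own design points; its defaults are the
published wild-type parameter values, and `na_params_mecp2()` carries the
null-model counterparts (reduced conductance, threefold late fraction,
steeper availability, slower −40 mV inactivation, faster fast recovery).

The voltage-clamp model is deliberately minimal: steady-state Boltzmann
activation `a∞(V)` (no m³ dynamics) with the upstroke smoothed by a 0.3 ms
rise filter, single-exponential inactivation whose time constant falls
e-fold per 25 mV of depolarization from 2.6 ms at −40 mV, a
voltage-independent non-inactivating fraction `f_late` standing in for the
(mechanistically unresolved, plausibly burst-mode) late current, and
biexponential recovery applied as a scale factor on the second pulse:

$$I(V,t) = G_{max}\, a_\infty(V)\, (V - E_{rev})\,
  r(t) \left[(1 - f_{late})\, e^{-\max(0,\,t - t_a)/\tau_{inact}(V)}
  + f_{late}\right],$$

with `r(t)` the rise filter and the inactivation clock starting at
`t_a = 7` rise time constants. Starting the decay only once the rise is
complete makes the peak attenuation voltage *independent*, so the peak
I–V relation carries the activation curve exactly and the analysis chain
recovers the generating `V_0.5`/`k` to three decimals on noiseless input —
the property the round-trip tests assert. `E_rev` defaults to 0 mV
(symmetrical 5 mM Na⁺), `G_max` to 1 pA/pF per mV, which puts peak
densities near −35 pA/pF, and `f_late` to 0.005 (half a percent of peak,
giving late densities of a few tenths of a pA/pF, the right order for
NMDG-subtracted murine records).

The AP generator is a waveform family, not an ionic model: a sigmoidal
upstroke (time constant 0.1 ms) multiplied by a monotone cubic
(`monoH.FC`) repolarization curve anchored so that the measured
APD~25/50/75/90~ of a noiseless beat land within 0.5 ms of the requested
targets; per-beat Gaussian jitter moves only the APD~90~ anchor, so BVR is
exercised with a known distribution (for jitter of SD σ,
`E[BVR] = σ√(2/π)`, which Monte-Carlo tests confirm). A consequence of
prioritising the APD targets is that the default upstroke velocity (about
250 V/s) overshoots the reported mean near 140 V/s; upstroke velocity is a
free parameter, not a generator target. The synthetic ECG is a train of
parameterised Gaussian bumps with annotations equal to the generator
fiducials, and the breath generator emits regular breaths with lognormal
Te jitter and replaces the breath nearest each requested apnoea time.

What the generator does *not* emulate — realistic channel gating dynamics,
capacitive/leak artefacts, electrode drift, T-wave morphology variation,
breathing-rate drift — bounds what passing tests show: they demonstrate
that the measurement chain is correct and unbiased under the stated noise
model, not that it is robust to every artefact of real recordings.

## Problem sizes used by the test-suite simulations

Simulation-based checks run at sizes chosen to make their Monte-Carlo error
comfortably smaller than the tolerance being asserted: 200 noisy replicates
for the kinetic parameter-recovery bias (2%-of-peak noise), 1000 random
breath series for apnoea-rule equivalence, 2000 series for the BVR
expectation, 10000 replicates for the t-test type-I error, and cohorts at
the published cell counts (41 vs 28 for the late-current comparison, 27 vs
29 for the AP comparison) for the directional group tests.

## Known limitations

* Absolute window-current and late-current magnitudes depend on per-strain
  `G_max` values that are not published; only shapes, ratios and
  directional group differences are testable.
* The in-vivo group tables (ECG and AP means over animals/cells) cannot be
  reproduced from deposited data; they are covered by directional
  synthetic-cohort tests only.
* The apnoea rule's exact historical windowing is unknowable from its
  description; both supported interpretations are explicit config choices.
* The AP waveform family is phenomenological; parameters that are not
  targets (upstroke velocity, APD~10~) are by-products of the shape.
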