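---
title: "Quantifying CSF dynamics from intrathecal infusion tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CSF dynamics from intrathecal infusion tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfinfusion)
```

## The measurement problem

Intrathecal infusion tests probe cerebrospinal-fluid (CSF) dynamics by
injecting fluid into the lumbar subarachnoid space and watching how the
pressures of the connected compartments react. Four channels are recorded
simultaneously: intrathecal pressure (ITP, at the injection site),
intracranial pressure (ICP, lateral ventricle), arterial blood pressure
(ABP) and central venous pressure (CVP), all in mmHg, acquired at 1 kHz and
analysed at 100 Hz. Two test designs are used:

* **Bolus infusion** — volume controlled: a rapid injection of a fixed
  volume (2 mL of Ringer's solution in the standard protocol, six
  repetitions 7 min apart). The immediate pressure peak and the spontaneous
  relaxation back towards baseline carry the information.
* **Constant-pressure infusion (CPI)** — pressure controlled: an automated
  apparatus holds ITP at a staircase of targets (six steps of 3.75 mmHg, 7
  min each) and the infusion rate needed to hold each step is logged.

From these, the package estimates the two classical lumped parameters of
CSF dynamics and quantifies inter-compartment communication.

## The compartment model

The analysis rests on the single-compartment nonlinear pressure–volume
model: compliance is inversely proportional to pressure, so pressure grows
exponentially with stored volume. The governing equation used both for
estimation (in closed form) and generation (as an ODE) is

$$\frac{dP}{dt} \;=\; \frac{\ln 10 \, P}{PVI}\left(I(t) -
\frac{P - P_r}{R_{out}}\right),$$

with $P_r$ the resting pressure, $PVI$ the pressure–volume index (the
volume in mL that raises pressure tenfold) and $R_{out}$ the outflow
resistance (mmHg per mL/min) opposing CSF absorption. Its closed forms are
the estimation formulas:

* a rapid bolus of volume $\Delta V$ raises pressure from $P_r$ to
  $P_p = P_r\,10^{\Delta V / PVI}$, inverted by
  `pvi()`: $PVI = \Delta V / \log_{10}\!\big((P_p - P_0)/(P_r - P_0)\big)$
  with reference pressure $P_0 = 0$ by convention (configurable for
  sensitivity analyses);
* the free relaxation from $P_p$ gives, at time $t$ minutes after the
  peak with relaxation pressure $P_t$ (`rout_bolus()`):
  $$R_{out} = \frac{t\,P_r}{PVI\,\log_{10}\!\left[\frac{(P_t/P_p)(P_p -
  P_r)}{P_t - P_r}\right]};$$
  relaxation pressures are read at 1, 2, 3 and 4 minutes and the four
  estimates averaged;
* at a settled constant-pressure step the volume balance is algebraic
  (`rout_cpi()`): $R_{out} = (P_a - P_b)/Q_{inf}$, where $P_a$ is the
  settled step pressure, $P_b$ the resting pre-infusion baseline and
  $Q_{inf}$ the holding infusion rate. $P_b$ is one value per session:
  using the previous step's pressure instead would make the quotient equal
  $R_{out}$ only at the first step, since $Q_{inf}$ at step $k$ balances
  the full elevation above rest.

The resistance channel is ICP when cranio-spinal communication exists;
in non-communicating animals the muted ICP cannot carry the relaxation and
the package falls back, flagged, to ITP.

## Signal conditioning

The conditioning chain (`preprocess_recording()`, `mean_trend()`) follows
the test's standard practice:

* **Outlier rejection** (`reject_outliers()`): z-score threshold
  $\sigma_{crit} = 3$. Statistics are computed on 30 s sliding windows —
  global statistics would let a large infusion transient mask genuine
  spikes (and vice versa); the window length is a package choice, as is
  replacing rejected samples by linear interpolation (deletion would break
  the uniform grid the filters need). A window with no spread rejects
  nothing, so constant segments pass through.
* **Pump band-stop**: 4th-order zero-phase Butterworth, stopband
  0.2–0.5 Hz, applied to all channels but only over the CPI span — the
  peristaltic roller pump that regulates pressure is the artifact source
  and runs only then.
* **Mean trend**: 4th-order zero-phase Butterworth lowpass at 0.1 Hz
  (10 s periods), removing cardiac (~1.7 Hz) and respiratory (~0.3 Hz)
  waves while keeping the bulk infusion response.

Numerically, these filters are designed in zero-pole-gain form and applied
as cascaded second-order sections. This matters: at a 100 Hz rate the
band edges are so small a fraction of Nyquist that the expanded
transfer-function polynomial is degenerate — rounding pushes poles outside
the unit circle and the filter diverges. Zero-phase application is
forward–backward with odd-reflection padding of one settling length and
step-state initial conditions per section; the input mean is removed and
restored so DC passes exactly.

Two practical consequences of *zero-phase* filtering shape the bolus
measurements. First, the filter spreads the sharp infusion front
symmetrically in time, contaminating the trend for about 12 s *before* the
injection; the resting pressure $P_r$ is therefore read 15 s before the
start (`guard_s`), where the trend is clean. Second, the filtered front
overshoots (ringing) by several percent of the step; the post-infusion
trend maximum `Pp` is the right quantity for mean-reaction sizes (peak
post minus peak pre of the filtered data), but for pressure–volume
arithmetic the package uses `Pp_raw` — the mean of the *raw* trace over
one respiratory cycle right after the front, which a boxcar cannot
overshoot and whose pulsatile components average out. The relaxation
clock for the $P_t$ read-outs is anchored at the infusion itself (1–4 min
post infusion); anchoring at the trend peak is available
(`pt_anchor = "peak"`) but mislabels the clock by the filter delay.

One further subtlety: under realistic parameter values the model's
relaxation time constant is tens of minutes, so 7-min bolus spacing leaves
later boluses starting from elevated pressure. The volume step still
gives the exact $PVI$ from the immediate pre-bolus pressure, but the
relaxation asymptote remains the session's resting baseline — so
`rout_bolus_mean()` takes that 5-min pre-infusion baseline (`Pr_rest`),
the defined baseline value for calculation, as the $P_r$ of the
relaxation formula. When relaxation does complete between boluses the two
coincide and the default (per-bolus $P_r$) is the textbook formulation.

## Pulse amplitudes, spectra and lags

Beat detection (`detect_beats()`) anchors on local maxima of the
0.5–5 Hz bandpassed trace (raw-trace maxima would merge beats across
respiratory excursions); per inter-anchor interval, systolic is the raw
maximum and diastolic the raw minimum, and the pulse amplitude their
difference. Amplitude statistics are arithmetic means of per-beat
amplitudes: 10 s pre-infusion versus 10 s from the trend peak for boluses,
and the settled step length for CPI.

`pressure_spectrum()` computes an averaged modified periodogram (60 s Hann
segments, 50% overlap, linear detrend) and labels the two largest
sub-5 Hz peaks that are not harmonically related (within 1.5 bins of an
integer multiple) as respiratory (lower) and cardiac (higher); peaks must
exceed 5× the median power in 0.05–5 Hz. Averaging the periodogram keeps
that prominence rule meaningful — in a single periodogram of white noise
the maximum bin alone exceeds 5× the median.

`xcorr_lag()` estimates inter-channel transmission delays as the argmax
of the normalized cross-correlation with parabolic sub-sample refinement,
recovering constructed lags (e.g. the ~0.31 s cranio-spinal delay) to
within 5 ms at 100 Hz.

## The synthetic cohort

Because raw recordings of this kind are rarely shareable, the package
generates its own verification data with known ground truth
(`simulate_animal()`). One animal is composed of:

* **Mean dynamics**: the compartment ODE integrated by fixed-step RK4 at
  the output rate with 10× substepping (compiled code), boluses as
  instantaneous volume additions (a finite-duration option exists), and
  CPI steps tracked by a proportional controller with steady-state
  feedforward (gain 2 mL/min per mmHg from the ~6 s closed-loop time
  constant; rate capped at 3 mL/min). The logged `q_inf` is the settled
  mean rate, as an infusion apparatus would report it.
* **Coupling**: ICP follows the ITP mean response through a gain
  `g_craniospinal` (1 = free communication; ~0.05 emulates an obstructed
  canal) and a 0.31 s delay; ABP and CVP add lagged first-order
  compensatory responses to ICP elevation (defaults sized to produce
  arterial reactions of a few mmHg and much smaller venous ones).
* **Pulsatility**: cardiac (1.74 Hz) and respiratory (0.30 Hz) harmonic
  series with 1/k decay — the analysis chain cares about discrete
  fundamentals plus harmonics, not waveform morphology. Cardiac amplitude
  grows with mean pressure (the pulsatility curve): CSF channels above a
  threshold (default 10 mmHg), blood channels above their own baseline.
* **Artifacts**: a 0.4 Hz pump oscillation on ITP during regulated steps,
  Gaussian sensor noise (SD 0.2 mmHg), optional extrasystoles.
* **Viscoelastic option**: multiplying each post-bolus relaxation
  deviation by $1 + \varepsilon e^{-t/\tau_v}$ emulates tissue
  viscoelasticity, which the compartment model ignores. With
  $\varepsilon = 0.3$, $\tau_v = 30$ s, the bolus estimator underestimates
  $R_{out}$ while the CPI estimator is unaffected — reproducing the
  qualitative bias reported for real tests.

A seed is mandatory and identical seeds give bit-identical recordings.
The generator writes the study-standard sessions: 5-min baseline plus six
boluses (7 min apart), and a separate CPI session of six steps — separate
because a combined session would start the staircase from a
still-elevated baseline.

What the simulator does *not* emulate: waveform morphology (dicrotic
notches, Lundberg waves), baroreflex/autoregulatory closed loops beyond
the linear gains, ventilation variability, movement artifacts, or
pressure-dependent (two-component) compliance. Passing the recovery tests
therefore shows the estimation chain is correct for Marmarou-type
dynamics with realistic oscillatory structure and noise — not that it is
robust to every pathology of real recordings.

## Verification strategy and problem sizes

Three layers of checks, all run by the test suite and
`scripts/acceptance.R`:

1. **Closed-form oracles**: on noise-free ODE output the peak equals
   $P_r 10^{\Delta V/PVI}$, `pvi()` recovers the index within 1% and
   `rout_bolus()` recovers the resistance within 2% at every timepoint.
2. **Parameter recovery**: 20 simulated animals ($R_{out}$ spanning
   40–90 mmHg/mL/min, $PVI$ 4–10 mL, default noise), full standard
   protocol, full pipeline; median absolute relative errors are well
   inside 10% (bolus), 5% (CPI) and 5% (PVI).
3. **Published-cohort reproduction**: the bundled six-animal reference
   tables pass through the summary stage to the headline numbers (e.g.
   bolus ΔITP 16.6 mmHg over the four communicating animals, CPI
   $R_{out}$ 74.8 ± 4.7 mmHg/mL/min). Subset rules are explicit: mean
   pressures and resistances average over communicating animals only,
   pulse amplitudes over all animals — the scheme recovered from the
   published arithmetic. Cohort dispersion is the sample SD (n − 1);
   rendering rounds half away from zero in decimal arithmetic.

Recordings are simulated at 100 Hz (the analysis rate; the 1 kHz
acquisition stage is covered by the decimation tests), ~2820 s per
session — sizes chosen so the whole verification runs in a few minutes on
one core while preserving the study's event timing.

## Known limitations

* The communication threshold (ratio 0.5 of ICP to ITP mean reactions) is
  a configurable convention; the reference animals split cleanly (ratios
  ≤ 0.08 vs ≥ 0.70), but borderline animals would need judgment.
* Harmonic labelling fails if the cardiac fundamental falls within 1.5
  bins of a respiratory harmonic.
* The CPI settling rule (fixed 60 s allowance, flagged when the residual
  trend drift exceeds 0.5 mmHg/min) is simple; steps on a slow drift are
  excluded rather than corrected.
* Extrasystoles are reported, not repaired; heavily ectopic segments
  should be excluded upstream.
* HDF5 I/O is not provided; CSV (recordings) and JSON (protocols) are the
  interchange formats.
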