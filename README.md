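# csfinfusion

Analysis of intrathecal infusion tests: multichannel pressure conditioning,
pulse and spectral features, bolus and constant-pressure infusion
quantification, and cerebrospinal-fluid (CSF) outflow-resistance estimation
— with a coupled-compartment simulator that generates verification data
with known ground truth.

## Who this is for

Infusion testing is the standard way to characterise CSF dynamics, both in
hydrocephalus work-up and in animal physiology studies. A lumbar catheter
injects fluid into the intrathecal space while intracranial (ICP),
intrathecal (ITP), arterial (ABP) and central venous (CVP) pressures are
recorded. This package implements the complete processing chain for such
experiments, from raw multichannel recordings (CSV) plus an
infusion-event annotation (JSON) to per-event reactions, per-animal
parameter estimates and cohort summaries.

## The model and estimators

The core is the single-compartment nonlinear pressure–volume model
(compliance inversely proportional to pressure):

    dP/dt = (ln10 · P / PVI) · ( I(t) − (P − P_r)/R_out )

* **PVI** (pressure–volume index, mL) — the volume that raises CSF
  pressure tenfold. From a bolus of volume ΔV raising pressure from P_r
  to the peak P_p:  `PVI = ΔV / log10((P_p − P_0)/(P_r − P_0))`.
* **R_out** (outflow resistance, mmHg/mL/min) — two independent
  estimators:
  * *bolus relaxation*: `R_out = t·P_r / (PVI · log10[(P_t/P_p)(P_p −
    P_r)/(P_t − P_r)])` at relaxation pressures P_t read 1–4 min post
    infusion, averaged;
  * *constant-pressure steps*: `R_out = (P_a − P_b)/Q_inf` per settled
    step, with P_b the resting pre-infusion baseline and Q_inf the
    holding rate, averaged over steps.
* **Cranio-spinal communication** — the ratio of intracranial to
  intrathecal bolus mean reactions; a muted ICP response (ratio < 0.5)
  indicates an obstructed spinal canal.

Signal conditioning follows the field's conventions: z-score outlier
rejection (σ = 3), a 0.2–0.5 Hz zero-phase band-stop for the
pressure-regulating pump's roller oscillation (applied over the CPI span
only), a 0.1 Hz zero-phase lowpass for mean trends, beat-wise pulse
amplitudes (systolic − diastolic), FFT spectra with cardiac/respiratory
fundamental identification, and cross-correlation lag estimation.

## Worked example

Simulate one communicating animal under the standard protocol (5-min
baseline; six 2-mL boluses 7 min apart; a separate session of six
3.75-mmHg pressure steps, 7 min each) and run the full analysis:

```r
library(csfinfusion)

comp <- compartment_params(Pr = 10, PVI = 6.6, Rout_true = 75)
wave <- waveform_params()        # 1.74 Hz cardiac, 0.30 Hz respiratory, ...
coup <- coupling_params()        # free cranio-spinal communication

bolus_proto <- standard_protocol(comp, "bolus")
cpi_proto   <- standard_protocol(comp, "cpi")
bolus_sim <- simulate_animal(comp, wave, coup, bolus_proto, seed = 1)
cpi_sim   <- simulate_animal(comp, wave, coup, cpi_proto,   seed = 2)

res <- analyze_infusion_test(bolus_sim$recording, bolus_proto,
                             cpi_sim$recording,
                             cpi_sim$ground_truth$protocol,
                             f_cardiac_hint = 1.74)
res$communication
#> <communication_call> ratio = 1.000 (threshold 0.50): communicating (n = 6)
res$rout_bolus
#> <rout_estimate> method = bolus: Rout = 74.8 mmHg/mL/min (n = 6, PVI = 6.68 mL)
res$rout_cpi
#> <rout_estimate> method = cpi: Rout = 75.0 mmHg/mL/min (n = 6)
res$summary$bolus
#>   channel     d_mean      d_amp
#> 1     ICP 18.8644425 1.86584987
#> 2     ITP 18.8692139 1.54313202
#> 3     ABP  3.5970953 0.62157674
#> 4     CVP  0.3023873 0.09396049
```

Both estimators recover the generating resistance (75 mmHg/mL/min) to
within a fraction of a percent, and the pressure–volume index (6.6 mL)
within ~1%. The bolus mean reactions (`d_mean`, mmHg) transmit fully from
the intrathecal to the intracranial space (communicating animal), with a
small compensatory arterial reaction and a near-null venous one; `d_amp`
is the accompanying pulse-amplitude increase.

The package also ships a six-animal ovine reference cohort (per-animal
summary tables of an acute infusion study) whose headline numbers the
summary stage reproduces:

```r
format_cohort(summarize_cohort(animal_summaries_from_reference()))
#>             metric mean   sd n
#> 1      bolus_d_itp 16.6  5.2 4
#> 2  bolus_d_itp_amp  2.4  0.3 6
#> ...
#> 9       rout_bolus 51.6 21.1 4
#> 10        rout_cpi 74.8  4.7 4
```

Mean-pressure metrics and resistances average over the four communicating
animals; pulse-amplitude metrics over all six.

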