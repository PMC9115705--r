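---
title: "Methods: the RV energetic model, its assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the RV energetic model, its assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvenergetics)
```

## The model

The premise is thermodynamic: almost all myocardial ATP comes from
oxidative phosphorylation, so the right ventricle's total mechanical
energy per beat is proportional to the oxygen it consumes per beat, with a
mixed-substrate yield of 20.2 J per ml O2 (`rv_constants()$k_o2`). The
glycolytic contribution is treated as negligible; the package exposes it
as the `anaerobic_offset` of the synthetic generator so its effect on the
regression intercept can be explored.

Total power output (TPO, J/min) is decomposed into isovolumic power —
raising the ventricular contents to ejection pressure without producing
flow — and stroke power. Two formulations are implemented.

* **Original variant** (`isovolumic_power_elbeery()`): the whole
  end-diastolic volume is raised to mean ejection pressure,
  `HR · mRV_EP · (RV_EDV − V0) · k`, with `k = 1.33e-4` J/(mmHg·ml) and the
  dead volume `V0` negligible by default (it is a field of `hemo_state()`
  for sensitivity analyses).
* **Adjusted variant** (`isovolumic_power_adjusted()`):
  `HR · (mRV_EP − RV_EDP) · RV_ESV · k`. This is a deliberate lower bound:
  only the residual end-systolic volume is charged, and only over the
  pressure rise the RV itself performs — in severe PAH the end-diastolic
  pressure is elevated by venous congestion and is, arguably, work done by
  the left heart. For any state with `RV_EDP ≥ 0` and `RV_ESV ≤ RV_EDV`
  the adjusted value never exceeds the original, a factor-wise inequality
  the test suite verifies on randomized states.

Stroke power has two routes:

* **Integrated** (`stroke_power_integrated()`), when instantaneous PA
  pressure and flow are both sampled: per beat, the trapezoidal integral
  of `P_PA · Q_PA` over the ejection window, divided by that beat's
  ejection period `T`, converted by `k` and averaged over the first five
  beats (a resting steady-state estimate).
* **Closed form** (`stroke_power_adjusted()`), when only scalar
  hemodynamics exist: `HR · mPAP · SV · k + 0.156 · PP`. The first term is
  the zeroth-harmonic (useful) stroke power; the second estimates
  oscillatory power as proportional to pulmonary pulse pressure. The
  0.156 coefficient is exposed in `rv_constants()` (`k_osc`) because its
  empirical provenance (a human pulmonary-circulation calibration) may not
  transfer to other species.

A caveat worth stating plainly: the two routes are not on the same scale.
The integrated formula divides the per-beat integral (with flow in
ml/min) by the ejection period rather than the full cycle, so it reports
the ejection-window average of `P·Q` — roughly `cycle/T` times the
per-cycle zeroth-harmonic power. Both are implemented exactly as defined;
mixing routes within one cohort analysis is not meaningful, and
`total_power_output()` keeps the chosen route explicit via its
`stroke_source` argument.

RV efficiency (`rv_efficiency()`) is useful stroke power,
`mPAP · CO · k`, over TPO. With the closed-form stroke route it lies in
(0, 1] by construction. Note that the pressure–volume product in the
useful-power definition requires the same mmHg·ml→J conversion as every
other term; it is applied so the ratio is dimensionless.

When flow is unmeasured, the parametric flow profile
(`invented_flow()`) substitutes for it: a half-sine over ejection damped
by `exp(−3t)`, whose negative lobe just past end-systole models pulmonary
valve regurgitation, linearly ramped to zero so the regurgitant window
lasts 0.04 s in total, and zero for the rest of diastole. The amplitude is
calibrated (`calibrate_amplitude()`) so the cycle-mean flow equals the
subject's cardiac output — a per-minute convention, chosen because
cardiac output is the quantity reported clinically. The damping exponent
treats time in seconds; since the amplitude is recalibrated per subject,
the profile's shape (not its absolute scale) is what the decay controls.

## Waveform processing

Beat segmentation (`segment_beats()`) works entirely on the smoothed
first derivative of the RV pressure waveform: ejection onset at each
prominent derivative maximum (the systolic upstroke) and end-systole at
the derivative trough within the cycle — end-systole in the RV under high
afterload is marked by the steepest pressure fall. Operating on the
derivative makes detection invariant to constant offsets (transducer
zeroing), which the suite checks. The derivative is smoothed with a
centred moving average of width 15 ms by default — wide enough to
suppress sample noise at 250–1000 Hz, narrow relative to any plausible
systolic interval; it is a tunable argument. Candidate onsets must clear
40% of the global derivative maximum and be separated by `min_rr`
(default 0.25 s, i.e. up to 240 bpm). A trailing beat is accepted when
the trace extends over at least 90% of the median period past the last
onset. Fewer than five full cycles is an error: the five-beat ensemble
convention needs at least that many.

Ensemble averaging (`ensemble_average()`) resamples each selected beat
onto the shortest beat's grid by linear interpolation and averages
pointwise. Linear interpolation is monotone and, at these sampling rates,
introduces error far below physiological variability; averaging five
identical beats returns the beat unchanged, and noise on independent
beats shrinks as `1/sqrt(n)` (verified by a 200-replicate Monte Carlo).

## The synthetic data generator

No subject-level clinical data ship with the package, so the generator is
a first-class module: it emulates the *distributional* structure the
analysis assumes, not any individual patient.

For the clinical cohort, each NYHA class draws its published marginals —
mPAP, cardiac output, ejection fraction, right coronary flow, and oxygen
extraction fraction (e.g. NYHA II mPAP 47.4 ± 11.7 mmHg; NYHA IV CO
3.5 ± 1.4 L/min, OEF 0.9 ± 0.08) — as independent truncated normals
(inverse-CDF sampling, so draws are deterministic under a seed and always
inside physiologic bounds). Cross-field coherence is enforced by
*deriving* the dependent quantities instead of drawing them:
`SV = CO/HR`, `RV_EDV = SV/EF`, `RV_ESV = RV_EDV − SV`. Fields the
published summary does not report carry declared assumptions, all exposed
in `cohort_spec()`:

| field | default | rationale |
|---|---|---|
| HR (bpm) | 78/82/86 ± ~12 by class | resting PAH heart rates, rising with severity |
| RV_EDP (mmHg) | 8/12/14 ± 3–5 by class | venous congestion rises with class |
| PP | (0.80 ± 0.10) × mPAP | pulse pressure scales with mean pressure in PAH |
| mRV_EP | mPAP + (5 ± 1.5) mmHg | small systolic RV→PA gradient |
| Sa | 0.95/0.93/0.91 ± 0.02–0.04 | mild desaturation with severity |
| Chb (g/ml) | 0.145 ± 0.015 | normal adult hemoglobin |

MVO2 is generated from the adjusted model's TPO through the coupling
constant with multiplicative Gaussian noise (`noise_cv`, default 0.05),
plus `anaerobic_offset/20.2`. With `noise_cv = 0` the power–oxygen
regression recovers slope 20.2 and intercept 0 exactly — a by-construction
identity the acceptance suite asserts at 1e-9.

The generator reproduces the qualitative severity structure: NYHA II
subjects cluster at high efficiency and low consumption, III/IV at low
efficiency and high consumption. What passing tests on this generator do
**not** show: that the model fits real patients (measured pressures have
reflected-wave morphology, measurement error sits on every channel, and
MVO2 is *not* generated from the model), nor that the independence of the
drawn marginals holds clinically (mPAP and CO are negatively correlated
in real PAH cohorts).

Waveforms (`generate_beat_waveforms()`) use a raised-cosine systole with
a flat diastolic floor: smooth, analytically integrable (the mean of the
raised cosine over the ejection window is `(1 + 2/π)/2`, which the
generator inverts to hit `mRV_EP` exactly), and with ejection onset and
end-systole at the quarter points of the systolic interval — recorded as
ground truth for segmentation oracles. The shape is a modelling
convenience, not a physiological claim.

The animal protocol generator (`generate_animal_timeseries()`) crosses
two afterload levels (banding: impedance increment 0 or 4 mmHg/(L/min),
raising mPAP by `ΔZ0 × CO`) with two oxygenation levels (Sa 1.00 or 0.75;
assumed extraction fractions 0.50 normoxic / 0.60 hypoxic), a baseline
set plus one set every 40 minutes over 4 hours, with 250 Hz waveforms on
request. Baseline sheep hemodynamics (HR 95, CO 5 L/min, mPAP 18 mmHg,
EF 0.45, Chb 0.10 g/ml) are textbook values for an anesthetized adult
sheep and are fields of `animal_protocol_spec()`.

## Validation statistics

`fit_power_oxygen_regression()` regresses TPO on MVO2 (that orientation,
matching the fitted equations the model is judged by) with t-based
two-sided tests and 95% CIs; `efficiency_oxygen_correlation()` does the
same with efficiency as response. `power_fraction_summary()` reports
mean ± SEM of the isovolumic/useful/pulsatile fractions by severity
stratum, with NYHA III and IV pooled and SEM reported as missing (not
zero) for single-record groups. `class_comparison_manova()` uses Pillai's
trace by default — robust to mild covariance heterogeneity; Wilks is
available, and with one between-group degree of freedom the two give
identical F and p — followed by per-variable Welch t-tests with a
Bonferroni factor of 3 (Welch, because group variances at n ≤ 8 cannot be
assumed equal).

A statistical limitation the package measures rather than hides: because
the generator places its noise on MVO2 (the regression's predictor), OLS
of TPO on MVO2 carries a small attenuation bias (about −1% at the default
5% noise) and its homoscedastic t-interval under-covers the true coupling
constant in repeated sampling. The Monte-Carlo coverage study in the test
suite documents this; errors-in-variables or heteroscedasticity-robust
intervals would be the remedy, at the cost of departing from the plain
OLS summary the model's validation convention uses.

## Numerical choices and problem sizes

* Trapezoidal integration throughout (stroke work, flow calibration);
  at 1 kHz the stroke-power error against a 10 kHz oracle is below 0.1%
  for the synthetic beat family.
* Calibration grids default to 1 kHz and are configurable; calibration is
  idempotent to 1e-9 relative.
* Window endpoints snap to the nearest sample; the integration window for
  the parametric profile extends to `t_es + 0.04` s so regurgitant
  (negative) work is captured, while measured flow integrates over
  `[t_start, t_es]` only.
* Consistency checks on read (`read_cohort_table()`) use a 1e-3 relative
  tolerance to absorb tabulation rounding; generated data are consistent
  to 1e-9.
* Monte-Carlo studies in the tests use 200–500 replicates; the
  within-cohort power studies use a cohort of 32/16/12 per class (the
  published class proportions scaled fourfold), since at the published
  n = 15 a single cohort's efficiency regression has only ~80% power at
  α = 0.05. Marginal-fidelity checks use n = 10,000 per class, where
  truncation shifts (≤ 2% of the mean for every field) dominate sampling
  error.

## Known limitations

* Tricuspid-regurgitant stroke work and post-systolic isovolumic
  contraction are not modelled; both would add to true total power.
* The closed-form oscillatory term is a human-calibrated proportionality;
  for other species the integrated route should be preferred when flow is
  measured.
* Asynchronously recorded RV/PA channels are treated as simultaneous; no
  alignment is attempted.
* The generator's independent marginals ignore clinically real
  cross-correlations; treat cohort-level statistics on synthetic data as
  checks of the machinery, not as clinical estimates.
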