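# rvenergetics

Right ventricular (RV) myocardial energetics from routine hemodynamics.

In pulmonary arterial hypertension (PAH) the right ventricle faces a
chronically elevated afterload, and its work output becomes limited by the
oxygen delivered through the right coronary artery. `rvenergetics`
implements an energetic model of the RV that couples total power output
directly to myocardial oxygen consumption, so that clinicians and
physiologists can estimate how much of a patient's RV energy budget is
spent on useful forward flow versus isovolumic pressure generation — and
therefore how close the ventricle is to its oxygen-supply ceiling.

## The model

Total mechanical energy per beat is coupled to oxygen consumed per beat at
the theoretical yield of oxidative phosphorylation,

```
TME (J) = 20.2 × VO2 (ml O2/beat)
```

and total power output (TPO, J/min) is the sum of isovolumic and stroke
power. Two formulations are provided:

**Original (Elbeery) variant** — isovolumic power charges the entire
end-diastolic volume to mean ejection pressure:

```
P_iso = HR × mRV_EP × (RV_EDV − V0) × 1.33e-4
```

**Adjusted variant** — a lower bound that charges only the end-systolic
volume over the pressure rise the RV itself performs:

```
P_iso = HR × (mRV_EP − RV_EDP) × RV_ESV × 1.33e-4
```

Stroke power comes either from waveform integration (trapezoidal
`(1/T) ∫ P_PA · Q_PA dt` over the ejection window, for subjects with a
measured instantaneous flow) or from the closed-form estimate

```
P_stroke = HR × mPAP × SV × 1.33e-4 + 0.156 × PP
```

whose second term estimates oscillatory (pulsatile) power from pulmonary
pulse pressure. When instantaneous flow is unmeasured, a parametric
("invented") flow profile — a damped half-sine over ejection with a 0.04 s
regurgitant window — is amplitude-calibrated so its cycle mean equals the
subject's cardiac output. RV efficiency is useful (non-pulsatile) stroke
power, `mPAP × CO × 1.33e-4`, divided by TPO.

The package also ships beat segmentation from the smoothed RV pressure
derivative (ejection onset at the derivative maximum, end-systole at its
trough), five-beat ensemble averaging, synthetic cohort/animal-protocol
generators with the published group-level distributions, and the cohort
validation statistics (power–oxygen regression with 95% CIs,
efficiency–consumption correlation, power-fraction summaries, and a
NYHA II vs III/IV MANOVA with Bonferroni-corrected post hoc tests).

## Worked example

```r
library(rvenergetics)

h <- hemo_state(hr = 75, mpap = 47.4, pp = 38, sv = 74.7, co = 75 * 74.7,
                mrv_ep = 52.4, rv_edp = 8, rv_edv = 162.4)
total_power_output(h, variant = "adjusted")
#> RV power breakdown (adjusted model), J/min:
#>   isovolumic          38.84
#>   stroke              41.25  (useful 35.32 + pulsatile 5.93)
#>   total               80.09
```

Of this subject's ~80 J/min total output, 38.8 J/min is isovolumic
(pressure generation without flow), 35.3 J/min drives forward flow and
5.9 J/min is lost to pulsation, for an RV efficiency of 0.44. The implied
resting oxygen demand is `80.09 / 20.2 ≈ 4.0 ml O2/min`.

A full synthetic cohort and its validation battery:

```r
coh <- generate_clinical_cohort(cohort_spec(), seed = 1)
fit_power_oxygen_regression(coh, "adjusted")
#> OLS: TPO_adjusted = 18.85 x MVO2 + 5.055  (n = 15)
#>   R^2 = 0.9936; slope p = 1.18e-15, 95% CI [17.94, 19.75]
#>   intercept p = 0.0598, 95% CI [-0.2425, 10.35]

class_comparison_manova(coh)
#> MANOVA (Pillai) NYHA_II vs NYHA_III_IV (n = 8, 7): statistic 0.7041,
#>   F(3, 11) = 8.723, p = 0.003017
```

The regression slope estimates the oxidative-phosphorylation yield
(theory: 20.2 J/ml O2) and the intercept the anaerobic contribution
(expected nil); the MANOVA shows that efficiency under both variants and
oxygen consumption separate mild from severe functional classes.

A thin command-line driver is installed at
`system.file("cli", "rvenergetics.R", package = "rvenergetics")` with
`simulate`, `compute`, `validate` and `report` subcommands.

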