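Package: rvenergetics
Title: Right Ventricular Myocardial Energetics from Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes right ventricular (RV) total power output, oxygen
    delivery and consumption, and RV mechanical efficiency from routine
    hemodynamic measurements, for the study of right heart function under
    elevated pulmonary afterload (pulmonary arterial hypertension, acute
    pulmonary banding).  Two model variants are provided: an isovolumic +
    stroke power formulation that charges the full end-diastolic volume to
    mean ejection pressure, and an adjusted lower-bound formulation based on
    end-systolic volume and the ejection-to-filling pressure difference with
    an oscillatory (pulse-pressure) stroke term.  Includes beat segmentation
    and ensemble averaging of sampled RV/PA pressure waveforms, a parametric
    pulmonary flow profile calibrated to cardiac output for use when
    instantaneous flow is unmeasured, synthetic clinical-cohort and animal
    protocol generators, and the cohort validation statistics
    (power-consumption regression, efficiency correlation, power-fraction
    summaries, and MANOVA severity-class comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
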