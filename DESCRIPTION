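Package: microvisc
Title: Noninvasive Personalized Estimation of Microvascular Blood Viscosity
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates whole-blood viscosity at low shear from routine
    clinical measurements (height, weight, blood pressure, heart rate and
    left-ventricular diameters) using a microcirculation capillary-network
    flow model. The capillary bed is idealized as a single Poiseuille tube
    whose latent radius is calibrated, stratified by body-mass-index class,
    through multiple linear regression against clinically measured
    viscosity. Includes the closed-form viscosity equation and its
    derivation from the flow model, BMI-stratified calibration and
    personalized prediction, an outlier-exclusion / split / balance-check /
    Pearson-correlation validation workflow, a seeded synthetic-cohort
    generator with planted ground truth for end-to-end testing, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
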