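Package: reciprocon
Title: Simulating and Analysing Informational and Normative Conformity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a dyadic circular-estimation task in which a participant
    and a (simulated) human or computer partner exchange perceptual estimates
    and take turns revising them, and analyses the resulting behaviour and
    synthetic region-of-interest BOLD signals. Provides circular geometry
    primitives (shortest-arc distance and interpolation), von Mises sampling
    and concentration estimation, partner construction with susceptible and
    insusceptible influence regimes, a generative cohort model of revision
    behaviour with participant-level random effects, linear mixed-effects
    analyses of informational (confidence) and normative (reciprocated
    influence) conformity, sliding-window reciprocity dynamics, and an
    event-locked fMRI ROI pipeline: HRF-convolved signal synthesis, nuisance
    residualisation, upsampling, epoch extraction, per-timepoint regression,
    leave-one-out peak inference, psychophysiological interaction analysis,
    and connectivity surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
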