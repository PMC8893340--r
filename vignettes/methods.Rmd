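---
title: "Simulating and analysing informational and normative conformity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing informational and normative conformity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(reciprocon)
library(dplyr)
```

## The task and the two routes to a change of mind

`reciprocon` simulates and analyses a dyadic perceptual estimation task
designed to pull apart two reasons for revising one's opinion towards a
partner's:

* **informational conformity** — revising because one's own estimate may
  be wrong, indexed by (low) confidence in the initial estimate;
* **normative conformity** — revising to reciprocate the influence one
  previously exerted over the partner, a social norm unrelated to
  accuracy.

A participant and a partner (believed to be human in half the blocks and
a computer in the other half) each estimate the angular position of a
briefly flashed target on a circle and the participant reports
confidence on a 1–6 scale. On *observation* (odd) trials the partner
then revises its estimate towards the participant's; on *revision*
(even) trials the participant revises towards the partner's, and the
task requires the revised estimate to lie between the two initial
estimates. A session is 4 blocks of 30 trials, one partner per block,
covering the 2 × 2 of cover story (human/computer) × susceptibility
(how strongly the partner lets itself be influenced).

Both conformity statistics are the same circular quantity, computed by
`shift_fraction()`: the shortest-arc distance the reviser moved, divided
by the shortest-arc distance between the two initial estimates.
*Revision* is this fraction for the participant; *influence* is the same
fraction for the partner. Angles are degrees in `[0, 360)` throughout
the public interface; exact antipodes in `move_toward()` are resolved
counter-clockwise, a deterministic and testable tie-break.

## The partner algorithm

Partners are simulated exactly as the task defines them:

* first estimates are von Mises draws centred on the target with
  concentration $\kappa = 7.4$, except on high-confidence trials
  (confidence 5–6) where the partner answers uniformly within ±50° of
  the participant's choice (±20° in the behavioural setting), applied
  wrap-aware on the circle;
* the influence a partner concedes is drawn from `[0, 0.2]` uniformly
  for *insusceptible* partners, and for *susceptible* partners from a
  mixture: `[0.7, 1]` w.p. 0.5, `[0.3, 0.7]` w.p. 0.2, `[0, 0.3]` w.p.
  0.3 (mean 0.57);
* the drawn influence is realised by shorter-arc interpolation
  (`partner_revision()`), so the recorded influence statistic equals
  the drawn value by construction. The task description does not say
  how the drawn influence becomes an angle; linear interpolation along
  the permitted arc is the unique choice that makes the recorded
  statistic equal the drawn one.

```{r partner}
set.seed(1)
mean(sample_influence(rep("susceptible", 1e4)))   # ~0.57
range(sample_influence(rep("insusceptible", 1e4)))
```

## The generative participant

The analysis models revision $r_t$ on revision trials from normalised
confidence $c_t = \text{confidence}/6$, the influence exerted over the
partner on the previous trial $\mathit{inf}_{t-1}$, and their
interaction. The cohort generator inverts this: it draws each
participant's random effects, evaluates the same linear predictor, adds
Gaussian residual noise, and truncates to `[0, 1]` (the task rule
forces the revised estimate onto the arc between the two initial
estimates).

Two generative modes mirror the two fitted models:

* **condition-specific** (`model = "lmm2"`): per-condition coefficient
  vectors, defaulting to the human set `(0.55, -0.3, 0.17, -0.21)` and
  computer set `(0.55, -0.37, 0.01, -0.03)` for (intercept, confidence,
  influence, interaction), with independent random intercept and random
  confidence and influence slopes;
* **joint** (`model = "lmm1"`): one 8-coefficient set over both
  conditions with the condition dummy coded 1 = human, 2 = computer
  (defaults `0.7, -0.33, 0.11, 0.07, -0.4, -0.1, -0.09, 0.21`), with
  random intercept and confidence slope.

The slope coefficients are the published fixed-effect estimates for the
corresponding models. The intercepts, random-effect SDs
(0.06/0.08/0.05), and residual SD (0.06) are **not** published
quantities; they are package design choices fixed once by pilot
simulation so that:

1. the linear predictor stays comfortably inside `[0, 1]` and the
   truncation of the residual is rare — measured recovery bias of every
   fixed effect is below 0.003 at cohort size 60, so REML estimates are
   effectively unbiased;
2. between-participant variability is realistic but does not overwhelm
   the fixed effects.

Perception is likewise an explicit invention (the analysis needs
confidence and accuracy to covary, but no perceptual parameters are
published): initial estimates are von Mises draws around the target
with `kappa_subject = 1.02`, chosen so the mean absolute error is
≈56.8°, matching the reported 56–57.5° range; an internal precision
signal (negative absolute error + Gaussian noise, SD 10°) is binned by
five fixed cutpoints into confidence 1–6, placing ≈24% of trials at
levels 5–6 so the partner's high-confidence branch is exercised. Any
monotone precision-to-ordinal map with nonzero top-level occupancy
would do; the cutpoints are frozen in `agent_params()` for
reproducibility.

The `ramp` parameter (default 0) adds a within-block drift,
`ramp * (trial/30) * (prev_influence - 0.35)`, emulating the
reciprocity learning seen in sliding-window analyses of real data; the
static default model has no trial-order dynamics, so this is the one
feature of the published behavioural pattern that is opt-in rather than
emergent.

```{r cohort}
cohort <- generate_cohort(12, seed = 7)
cohort
```

## Behavioural analysis

`annotate_trials()` recomputes both statistics from the recorded angles
alone, adds `conf_norm`, the lagged influence, and the condition dummy,
and drops trials with zero initial disagreement (undefined fractions)
with a logged count — the original report is silent on exclusions, so
dropping-with-count is the package's choice.

`fit_lmm1()`/`fit_lmm2()` fit the joint and single-condition mixed
models with REML via `lme4`/`lmerTest`: independent (diagonal) random
effects, matching the stated $b_{ks} \sim N(0, \sigma_k^2)$ structure;
fixed effects tested by F statistics with Satterthwaite denominator
degrees of freedom (the square of the Satterthwaite t; numerator df 1);
95% CIs from the same df; Holm-adjusted p-values reported alongside raw
ones, with the family defined as the fixed effects of one fitted model.
The single-condition model keeps the interaction as a fixed effect only
— the fully varying version is overparameterised — and the shipped
random structure has lower BIC than the variant without a random
confidence slope on simulated cohorts (verified in the test suite).
Condition is coded 1/2 rather than a centred contrast because the
published coefficients depend on that coding. Singular fits are
flagged; if a random structure fails outright the fit falls back to a
simpler one and says so.

```{r fits}
ann <- annotate_trials(cohort$trials)
fit_h <- fit_lmm2(ann, "human")
tidy(fit_h)
```

`sliding_window_revision()` averages revision in 5-trial windows moved
by 1 trial within each block (15 revision trials give 11 windows);
`signed_rank()` wraps the two-sided Wilcoxon signed-rank test (exact
for n ≤ 25 without ties, normal approximation with continuity
correction otherwise; all-zero differences return a degenerate flag
with p = 1); `holm_adjust()` is the step-down Holm correction.

### Parameter recovery

`recovery_experiment()` is the core validation: generate replicate
cohorts of 60 from the packaged coefficients, refit, and compare. Over
100 replicates per model the mean estimates recover every generating
coefficient within three Monte-Carlo standard errors of the mean
(a simultaneous band across the ~13 coefficients checked; per-coefficient
2-SE bands would false-alarm on about half of runs even for an exactly
unbiased estimator), and 95% CI coverage lies within [90%, 99%].

## Synthetic ROI BOLD

No voxel data exist in scope; `synthesize_roi_signal()` produces
single-ROI time series with known ground truth:

* `build_event_schedule()` lays the six trial events (stimulus stream,
  initial estimate, confidence, partner estimate, revision/observation
  screen, final display) on a per-run clock with uniform 1.5–4.5 s
  jitters, 1.5 s partner display, 3 s final display, TR 3.74 s; runs
  land near 12–13 minutes, inside the 12–17 minute band of the
  emulated scan runs;
* events evoke a canonical double-gamma HRF (peak ≈5 s, undershoot
  ≈15 s, unit peak, no derivative terms — the analysis operates on raw
  time courses, so one fixed shape suffices for recovery testing)
  scaled by a baseline plus linear loadings on z-scored trial
  modulators (`encoding_spec()`); the default injects negative
  confidence encoding in both conditions and negative
  confidence-by-influence encoding on human revision trials only;
* noise is AR(1) (ρ = 0.3) plus white noise plus a small mixture of six
  random-walk motion regressors, so residualisation is exercised
  non-trivially. The original noise structure is of course unknown;
  these defaults stress but do not break recovery at n = 20.

`synthesize_coupled_pair()` provides PPI ground truth: within each
revision-screen epoch the target region tracks the seed with gain
$\alpha + \gamma_c z_c + \gamma_i z_i + \gamma_{ci} z_{ci}$ (z-scores
over all revision trials), plus noise.

## ROI pipeline

The analysis chain mirrors standard event-locked ROI practice:
per-run OLS residualisation on the motion regressors
(`residualize()`), cubic-spline upsampling to 0.2 s (`upsample()`; the
source analysis says only "upsampled", so the natural cubic spline is
pinned by fixture tests), and extraction of 75-point epochs anchored
exactly 1 s before each event onset (`extract_epochs()`; nearest-grid
alignment, error ≤ 0.1 s; edge epochs dropped with a warning).
`beta_timecourse()` then fits an OLS regression across trials at each
of the 75 time points — modulators z-scored per participant, never
orthogonalised, so correlated regressors compete for variance — and
concatenates coefficients into beta time courses. Whether the original
per-timepoint fits pooled same-condition runs or averaged per-run fits
is unstated; the package pools trials across runs (both same-condition
runs enter one regression).

`loo_peak_test()` implements leave-one-out group inference: for each
participant the group-mean curve excluding them is computed, the peak
is the time of maximal absolute mean (positive or negative; earliest
time on ties), and the left-out participant's beta there is collected;
the collected values are tested against zero by signed rank.

One property of this procedure deserves emphasis. Leaving the tested
participant out makes each collected value *individually* unbiased
under a null of zero-mean betas (verified by simulation in the test
suite). It does **not** make the group test exact: all n peak
selections are driven by nearly the same data, so the collected values
share the selection event and are positively correlated, and the
signed-rank test on them is anticonservative under a global null
(simulated rejection ≈0.18–0.33 at α = 0.05 depending on the temporal
smoothness of the null betas, n = 15–20). The package implements the
procedure as published and reports this calibration honestly rather
than altering the method; significant LOO results on weak or noisy
effects should be read with this in mind.

`ppi_timecourse()` regresses target epochs on seed activity, the
behavioural modulators and *all* seed × modulator interactions
(including the seed × confidence × influence triple interaction, which
"all interaction terms" implies; `include_triple = FALSE` drops it),
with every main effect controlled. `ppi_window_coefficients()`
averages coefficients over the 2–3 s post-onset window (6 samples at
0.2 s), and `connectivity_grid()` evaluates the implied
modulator-dependent seed slope on a `[-2, 2]²` z-score grid with step
0.25.

```{r roi, fig.width = 6, fig.height = 3.5}
tr <- annotate_trials(build_session(seed = 11))
sch <- build_event_schedule(tr, seed = 12)
sig <- synthesize_roi_signal(sch, tr, seed = 13)
ep <- roi_epochs(sig, sch, tr, event = "t5", role = "revise",
                 condition = "human")
mods <- data.frame(
  conf = ep$trials$conf_norm,
  inf = ep$trials$prev_influence,
  conf_inf = ep$trials$conf_norm * ep$trials$prev_influence,
  log_rt = log(ep$trials$rt_revision),
  block = ep$trials$block
)
bt <- beta_timecourse(ep$epochs, mods)
autoplot(bt, predictors = c("conf", "conf_inf"))
```

## The end-to-end pipeline

`run_pipeline()` chains every stage — cohort, annotation, both mixed
models, sliding windows with the late-window susceptible vs
insusceptible contrast, ROI synthesis and LOO inference per condition,
and PPI with its connectivity surface — under a single seed; rerunning
with the same configuration and seed reproduces every number.

## What the synthetic data do and do not show

The generators emulate the statistical structure the analyses assume:
the stated partner distributions, the mixed-model generative form with
its random effects, HRF-convolved linear encoding with autocorrelated
noise, and epoch-level multiplicative coupling. Passing tests therefore
demonstrate that the implementation is faithful and that the estimators
recover known truth under that structure. They do not show that real
behaviour follows the linear model (real revisions are bounded,
heteroscedastic and serially dependent in ways the truncated-Gaussian
residual only approximates), nor that real BOLD noise is AR(1), nor
anything about the anatomical claims; headline statistics bound to the
real 60-participant dataset (Wilcoxon W values, the 0.34 mean revision,
performance ratings) are deliberately out of scope.

## Problem sizes and numerical choices

Validation experiments in the test suite and acceptance script use 100
replicate cohorts of 60 participants for parameter recovery, 10
replicate groups of 20 synthetic participants for ROI power, 500
replicates for LOO calibration, and 12 participants for PPI recovery —
sizes chosen to keep Monte-Carlo error well below the effects being
verified while completing comfortably on a single CPU. Degenerate
inputs are handled explicitly: zero initial disagreement yields missing
statistics (dropped with a count), all-zero signed-rank differences
yield a degenerate flag, constant modulators yield flagged `NA`
coefficients, rank-deficient nuisance matrices drop collinear columns
with a warning, and singular mixed-model fits are flagged rather than
hidden.
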