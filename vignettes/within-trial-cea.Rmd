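---
title: "Within-trial cost-effectiveness analysis with ceatrial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-trial cost-effectiveness analysis with ceatrial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

`ceatrial` implements a within-trial economic evaluation of a two-arm
randomized trial in which an internet-delivered emotion regulation therapy is
added to treatment as usual (TAU) for adolescents with nonsuicidal
self-injury (NSSI) disorder. The trial structure the package assumes is:
randomization of about 166 adolescents to intervention + TAU versus TAU only,
weekly self-rated NSSI counts during and shortly after the 12 treatment
weeks, and three assessment points — baseline, week 16 (1 month
posttreatment, the primary endpoint) and week 24 (3 months posttreatment) —
at which clinician-rated past-month NSSI counts, KidScreen-10 quality-of-life
scores and parent-reported resource use with a 12-week recall (8 weeks for
the final window) are collected.

The economic question is the incremental cost per unit of health gained:
per NSSI episode averted, per additional remission (no NSSI in the past
month), and per quality-adjusted life year (QALY). Because no
participant-level data from such a trial are distributable, the package
ships a synthetic trial generator that reproduces the statistical structure
the analysis pipeline assumes, so every stage is testable end to end.

## Costing

Resource-use quantities are priced per category and converted once:

* directly priced categories (health care visits, medication, supplements,
  social support): quantity x unit cost;
* informal support and unpaid-work absence: hours x post-tax hourly wage;
* paid-work absence (human capital approach): days x gross daily salary
  including payroll fees;
* school absence: days x annual cost per pupil / school days per year;
* school presenteeism: the same per-day cost additionally multiplied by the
  reported fractional performance loss.

Money is handled in a fixed order: price in base-year local currency, uprate
by the consumer price index ratio, convert to USD by the purchasing power
parity rate. The order is a convention (the operations are scalar
multiplications and commute); fixing it makes results bit-stable. No
discounting is applied: the horizon is under one year. The intervention cost
is therapist time priced at a psychologist's hourly rate and is assigned to
the 1-month-posttreatment recall window, which covers the treatment weeks;
it enters both perspectives, for intervention-arm participants only.

The *health care* perspective keeps visits, medication, supplements and the
intervention cost; the *societal* perspective adds social support, informal
support, school absence/presenteeism and parental productivity losses, so a
participant's societal total can never be below their health care total.
Unknown categories raise an error rather than being dropped: a costing
omission should be loud. Unit costs, CPI values and the PPP rate are
configuration data; the bundled `inst/extdata/unit_costs.json` is an
illustrative synthetic tariff of plausible Swedish magnitudes, not an
official price list. Baseline-period costs are never added into follow-up
accumulations; they serve only as adjustment covariates. Accumulated cost at
3 months is exactly the 1-month accumulation plus the 1-to-3-month period
cost.

## Health outcomes

KidScreen-10 scores are mapped to CHU9D-style utilities through a pluggable
linear `mapping_model()`. Published mapping algorithms are tariff-specific
and live in external papers, so the package deliberately does not hard-code
one; the bundled default (utility = 0.13 + 0.01 x score, clamped to [0, 1])
is a documented fixture whose metadata records the mapping literature's mean
absolute error of 0.0946. Mappings must be monotone nondecreasing. Utilities
are clamped to [0, 1] because the exact instrument floor is tariff-specific;
the bounds are configurable.

QALYs are the area under the piecewise-linear utility trajectory
(trapezoidal rule, assessment weeks converted to years as week/52), assuming
a constant rate of change between assessments. Remission at an assessment
point is exactly zero past-month NSSI episodes.

## The NSSI count model

Weekly counts are modeled by a zero-inflated negative binomial mixed
regression: structural zeros with constant probability, and a negative
binomial component whose log-mean carries intercept, arm, week, and
arm-by-week terms plus a bivariate Gaussian random intercept and slope per
participant. The arm-by-week coefficient exponentiates to the weekly
incidence rate ratio; between-group rate ratios at the assessment weeks are
derived as `exp(b_arm + week x b_int)`.

The marginal likelihood is implemented in the package: per participant, the
bivariate random effect is profiled by a damped Newton iteration (analytic
gradient and Hessian of the joint log-density, vectorized across
participants) and integrated by a Laplace approximation, with adaptive
Gauss-Hermite quadrature available as a higher-accuracy option. At this
design — roughly 17 observations per participant — Laplace is the standard
choice for this model class, and the test suite verifies it against dense-grid
numerical integration, against quadrature, and against an independent
implementation (`glmmTMB`), which agrees to at least four decimals in all
parameters on simulated trials.

Numerical choices worth recording: time is coded in weeks from randomization;
the zero-inflation component is intercept-only (the data provide no covariate
structure for structural zeros); the optimizer (`nlminb` on
log/logit/atanh-transformed parameters, bounded away from degenerate
variance components) restarts from three fixed jittered starts with the best
likelihood winning and ties broken by the first start; Wald intervals come
from the numerical Hessian at the optimum. All-zero count data are rejected
as degenerate (the zero-inflation probability is unidentified). Non-PD
subject blocks during the inner Newton are ridge-damped.

## Missing data

Follow-up missingness is handled by multiple imputation by chained equations
with predictive mean matching, written in this package: Bayesian linear
regression per incomplete variable (posterior draws of coefficients and
residual variance), type-1 matching against the `k` nearest observed donors
by predicted mean, so every imputed value is an observed value of its
column. The randomization arm is always a predictor and never imputed;
observed cells are never altered. Defaults — M = 20 imputations, 20 cycles,
5 donors — follow common practice and are configuration, not data-derived;
the simulation tests scale M down (5) to keep runtimes desk-sized without
changing the algorithm.

## The CEA engine

Costs and effects are analyzed jointly at each follow-up: ordinary least
squares of the outcome on the arm indicator plus its baseline covariate
(baseline costs for costs, baseline utility for QALYs; remission is left
unadjusted). With identical regressors in both equations the
seemingly-unrelated-regression estimator collapses to per-equation least
squares, so the cross-equation correlation between costs and effects — which
is what motivates joint modeling — is carried by the patient-level bootstrap:
within each imputed dataset, participants are resampled with replacement
*stratified by arm* (preserving the randomization ratio) and both equations
are re-estimated on the same resample. Each (imputation, bootstrap) pair runs
on its own deterministic substream of one master seed.

Pooling across imputations uses Rubin's rule for the point estimates (mean
of per-imputation estimates) and percentile intervals over the stacked
M x B draws for uncertainty. Stacking is the standard pragmatic choice when
a bootstrap is nested inside imputations and is declared here as a design
decision, not an inference from any publication.

Post-estimation: the ICER is the ratio of pooled point estimates and is
always reported with its plane quadrant, because a bare negative ratio is
ambiguous (dominant and dominated look identical). ICER percentile
intervals are computed over per-draw ratios, excluding (and counting) draws
with |delta-effect| below machine tolerance; such draws still contribute to
net monetary benefit and the acceptability curve, which are well-defined
where the ratio is not. NMB is `lambda x dE - dC`; the acceptability curve
is the fraction of draws with strictly positive NMB on a willingness-to-pay
grid (default 0 to 200,000 by 1,000, covering the Swedish reference value of
84,000 per QALY). Plane quadrants use the convention NE = (more effective,
more costly); draws exactly on an axis are assigned east/north (zero counts
as effective / as costly), a measure-zero tie rule that keeps proportions
summing to one. For NSSI frequency the incremental effect is flipped to
"episodes averted" (control minus intervention) so improvement is positive.

## The synthetic trial generator

`generate_trial()` emulates the study conditions: 83 participants per arm;
17 weekly NSSI observations; assessments at weeks 0, 16, 24; weekly counts
from the same zero-inflated negative binomial mixed model the analysis fits
(baseline observed mean 2.8 episodes/week, zero inflation 0.25, dispersion
1.5, random intercept SD 0.6, random slope SD 0.02, control-arm weekly trend
0.986, weekly treatment IRR 0.966); baseline utility 0.632 (SD 0.04) with an
arm utility gain of 0.03 reached at week 16 and maintained; and ~8%
missing-at-random follow-up data whose probability depends only on observed
baseline severity. Past-month counts at assessments are drawn at four times
the weekly mean.

Costs are simulated as log-normal per-category quantities (SD 0.7 on the log
scale) whose log-means share a latent severity factor with the random
intercept and the utilities; the loading is scaled by `cost_outcome_corr`
(default -0.3), reproducing the right-skewed costs and the negative
cost-outcome correlation a real trial of this population shows. The default
quantity calibration yields baseline arm-level costs of roughly $4,000
(health care) and $20,000 (societal) per 12 weeks under the bundled tariff,
and therapist time averages 1,550 minutes so the intervention cost lands
near $3,550. These calibration constants are fixtures chosen once to match
the order of magnitude of published adolescent NSSI trial summaries; they
are not estimates of any real tariff or dataset. The trial report the
generator is calibrated against prints no distributional forms for costs or
utilities, so the log-normal/shared-factor construction is a declared design
choice of this package.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: item-level questionnaire behavior, informative
(MNAR) dropout, site effects (deliberately ignored, matching the analysis),
therapist behavior, and remission proportions calibrated to any particular
trial (remission emerges from the count model rather than being targeted
directly, and its arm difference is smaller than in the motivating trial).

## Problem sizes used in the test suite

Simulation-based checks run at sizes chosen to balance Monte-Carlo precision
against desk-scale runtimes, and these choices are the package's own:
parameter recovery for the count model uses 20 replicates of 400
participants x 17 weeks; null calibration of the percentile intervals uses
200 replicates at the default trial size with M = 5 and B = 500 (scaled down
from the production defaults of 20 and 5,000); imputation recovery uses 50
masking seeds; the bootstrap is validated against exhaustive enumeration of
all 27 resamples of a 3-value arm at B = 100,000.

## Known limitations

* The Laplace approximation can be slightly biased for very sparse counts;
  the quadrature option exists for verification but is slower.
* ICER percentile intervals inherit the usual sign-ambiguity of ratio
  statistics; always read them with the plane quadrants.
* The imputer assumes approximately linear relations among analysis
  variables; it imputes accumulated totals directly rather than per-period
  components.
* No extrapolation beyond the trial horizon, no discounting, and no
  value-of-information analysis are provided by design.

## A short tour

```{r}
library(ceatrial)

cfg <- cea_config(trial = trial_config(seed = 1), M = 5, B = 500,
                  imputation_iterations = 5, seed = 1)
bundle <- run_pipeline(cfg)
bundle$results[["societal.qaly_1m"]]
head(as.data.frame(bundle$summary))

d <- generate_trial(trial_config(seed = 1))$weekly
names(d)[names(d) == "nssi_count"] <- "count"
fit <- fit_zinb_glmm(d)
fit
```
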