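---
title: "Estimating per-protocol survival effects under treatment switching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating per-protocol survival effects under treatment switching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In oncology trials the protocol often permits control-arm patients to cross
over to the experimental drug after disease progression. The intention-to-
treat (ITT) contrast then answers "what is the effect of *assignment*", not
"what is the effect of *sustained treatment*": when the experimental drug
works, the benefit received by switchers dilutes the ITT overall-survival
comparison. Decision makers — particularly in health-technology assessment,
where the comparator world has no access to the new drug — need the
per-protocol (PP) estimand: the contrast of the strategies *always treat
with the experimental drug* versus *always treat with the control drug*,
with switching and loss to follow-up (LTFU) eliminated.

The obstacle is treatment-confounder feedback. Post-progression covariates
such as performance status (ECOG) and target-lesion size (TLS) both drive
the decision to switch and predict death, and are themselves affected by
earlier treatment. Conditioning on them in an outcome regression blocks
part of the treatment effect and opens collider paths; ignoring them leaves
the switching selection uncorrected. g-methods resolve the dilemma:

* **IPCW** (inverse probability of censoring weighting) censors a subject
  at the deviation event (crossover, or LTFU) and re-weights the remaining
  comparable person-time by the inverse of the modelled probability of
  having remained event-free, creating a pseudo-population in which the
  deviation is independent of the measured covariates;
* the **parametric g-formula** fits models for each time-varying covariate
  and the discrete death hazard within each arm, then Monte-Carlo
  simulates covariate and outcome histories with treatment forced to the
  strategy value and censoring eliminated.

`ppswitch` implements both on a common discrete-time (30-day interval)
person-time representation, together with the ITT battery, the naive PP
estimators (exclude switchers / censor at switching) that the g-methods are
meant to replace, subject-level bootstrap inference, and a synthetic trial
generator whose mechanism can be *intervened on directly* to produce the
true counterfactual risks — the ground truth against which everything else
is validated.

## Data representation

All estimators consume a person-time table: one row per subject per
complete month `k = 0, 1, ...`, carrying the randomized arm `Z`, the
treatment actually received `A_k`, time-varying covariates `L_k`
(progression `dp`, intracranial progression `icp`, `ecog_tv`, `tls`, time
since progression `tdp`), and indicators for death (`outcome`, the event
"died by the end of interval k+1" attached to row `k`) and pooled
LTFU/administrative censoring (`censored`). Conventions the code fixes
(the field leaves them implicit):

* death takes precedence over censoring in the same interval;
* switching is recorded at the start of the interval of the first
  experimental dose, so the switch interval itself is already
  "off-protocol" and is removed when censoring at switching;
* partial final intervals are not emitted — only complete 30-day intervals
  contribute rows;
* LTFU and administrative censoring are pooled into one indicator and
  modelled jointly.

## Discrete-time survival machinery

The discrete hazard `h_k = Pr(death in interval k | alive at its start)`
is estimated either nonparametrically (deaths over at-risk mass per month,
the Kaplan-Meier life table; subjects censored in an interval count as at
risk during it) or by pooled logistic regression with a quadratic
polynomial in time as the default baseline-hazard shape (a saturated
step function and 5-knot natural cubic splines are available). Survival is
the product limit `S_k = prod(1 - h_m)`. Effect measures at the horizon
(48 months by default):

* `dHR` — the discrete hazard ratio, `exp` of the arm coefficient of the
  pooled logistic outcome model (close to the Cox HR when hazards are
  small);
* `cHR` — the cumulative hazard ratio. Two formulations coincide for
  small hazards: `-log S_e(48) / -log S_c(48)` (the default) and the ratio
  of summed hazards (available via `chr_method = "sum_hazard"`); every
  output records which was used;
* `RR` — the ratio of cumulative risks at the horizon.

Spline bases place 5 knots at the 5th/27.5th/50th/72.5th/95th percentiles
of the fitting data; knots and category codes are frozen at fitting time
so prediction is deterministic, and unseen categories at prediction time
are an error, not a silent level.

## IPCW

Weights are built separately per deviation process and per arm.
Deterministic knowledge enters as structural weight-of-1 rules:
experimental-arm subjects cannot switch, and control subjects cannot
switch before progression; the non-deterministic switching models are
fitted on control-arm post-progression person-time only. The denominator
model is covariate-conditional; the numerator model is time-only and
produces stabilized weights as the cumulative ratio of event-free
probabilities. Unstabilized weights are the cumulative inverse of the
denominator alone. The weighted outcome model contains the randomized arm
and linear plus quadratic time — never the confounders.

A subtlety that the package documents and tests rather than hides: with
one-sided switching, eligibility for the switching process opens at
progression, so the time-only numerator accrues over *subject-specific*
windows. It therefore does not cancel within months of a weighted
Kaplan-Meier and effectively re-weights the population by progression
time, which predicts death. On data where the weight models are exactly
the generating mechanism, the unstabilized weights recover the oracle
counterfactual risk while the stabilized point estimate is shifted; when
every subject progresses at entry (a shared eligibility clock) the two
estimators coincide exactly, which is the textbook situation the
stabilization argument assumes. Consequently `ipcw_pp_analysis()` defaults
to stabilized weights for comparability with the sensitivity-table convention of applied IPCW analyses,
exposes `stabilized = FALSE`, and the package's own truth-recovery checks
use the unstabilized estimator.

Further weighting tools mirror applied practice: percentile truncation
over pooled person-time (truncating both bounds to the median reproduces
the unweighted analysis exactly — a useful structural check), mean/SD/
min/max diagnostics with an extreme-weight alarm (mean off 1 by more than
0.1, or max above 10 times the mean), univariate covariate screening
(retain when p <= 0.20 or the odds ratio leaves [0.75, 1.33], with AIC
reported), and a sensitivity grid over labelled weighting specifications.

## Parametric g-formula

Each arm is analysed as a separate observational study. Covariate models
are fitted in a fixed within-month order — ECOG, TLS, then progression,
then intracranial progression — chosen to match the shipped generator's
update order (covariate drift happens before the month's progression
draw); the order is configurable through the ordered covariate list of
`gformula_spec()`. Model families: logistic hazards for binary absorbing
covariates (fitted only where the lagged value is 0, simulated as sticking
at 1), a monotone "worsening increment" logistic for the ordinal ECOG
(fitted and simulated only below its ceiling — this matches a monotone
deterioration process; an unrestricted multinomial family is deliberately
out of scope), and pooled linear regression for TLS with the
maximum-likelihood residual SD (the root-mean-square residual) used for
simulation noise, values clamped at the measurement floor with a logged
clamp count. Transition-type models exclude month-0 rows, which repeat the
baseline value by construction. The death model is fitted on
post-progression person-time only and death probability is structurally 0
before progression.

Simulation resamples observed baseline rows with replacement (preserving
the joint baseline distribution), forces treatment to the strategy value
(or draws switching from a fitted model under the *natural course*),
never simulates censoring, and runs an automated audit afterwards:
intervention held, absorbing states monotone, death gated by progression,
risk non-decreasing. The natural-course diagnostic compares simulated
covariate means and cumulative risk against the observed arm month by
month — a model set whose natural course drifts from its own data is
misspecified and its counterfactuals should not be trusted.

## Inference

Confidence intervals come from a nonparametric bootstrap that resamples
*subjects* (all person-time rows of a subject move together), stratified
by randomized arm so arm sizes are preserved, and re-runs the entire
procedure — weight estimation plus outcome fitting, or g-formula fitting
plus simulation — on every replicate. Replicates on which a model fails
are dropped and counted, never retried; a result with more than half
failed replicates is flagged unreliable. Intervals are percentile-based
(type-7 empirical quantiles); defaults are 1000 replicates for ITT/IPCW
paths and 500 for the g-formula.

## The synthetic trial generator

The generator is first-class code, not a test fixture: it defines the
study conditions under which the estimators are validated. Defaults
emulate a 275-patient (138 control / 137 experimental) two-arm trial over
48 months:

* baseline covariates drawn to match the baseline table of a typical first-line ALK-inhibitor trial
  (age ~ N(58, 11) truncated to [25, 90], ECOG 39/55/6%, lognormal TLS
  around 45 mm, four-level diagnosis stage, lung involvement,
  randomization strata from brain metastases x prior chemotherapy, etc.);
* monthly logistic hazards for progression (median PFS just under a year
  on control; the experimental drug shifts the logit by -0.30), death
  (gated on progression; logit shifted by treatment -0.20, per-decade age
  +0.25, ECOG +0.60, TLS +0.25 per 10 mm), and a small constant LTFU/AC
  hazard (about 0.4% per month, ~10% cumulative);
* treatment-confounder feedback: prior treatment slows TLS growth and
  ECOG worsening, and both covariates feed the switching and death
  hazards;
* one-sided switching, possible only post-progression, with hazard
  concentrated shortly after progression (time-since-progression slope
  -0.70, steeper at high ECOG via an ECOG x TDP interaction -0.25),
  strongly decreasing in age (-0.60 per decade, plateauing below 43
  years — the youngest patients behave alike; switchers in trials of
  this kind tend to be notably younger), and calibrated so that about
  47% of controls ever switch (47.7% at n = 10,000).

These choices were made once, by Monte-Carlo calibration against the
marginals typical of trials of this design (47% crossover, roughly a
third to a half of subjects dying by month 48, 48-month counterfactual
risks near a reference scale of 0.56/0.41), and are not revisited. The
configuration deliberately reproduces a characteristic weight pathology
of applied IPCW analyses: under the full prognostic weight
model the stabilized weights are tame, while dropping the
time-since-progression terms leaves the denominator unable to shut off
the hazard after the post-progression window, so young long-surviving
non-switchers accumulate extreme weights and the weight SD inflates by an
order of magnitude — the same qualitative signature (SD and maximum
exploding, mean still near 1) reported for the trial re-analysis.

`simulate_truth()` re-runs the same mechanism with switching and
censoring hazards forced to zero and treatment forced to the strategy
value: the resulting empirical risk curve is the estimand's ground truth
up to Monte-Carlo error `sqrt(r(1-r)/n_oracle)`. Under the defaults the
48-month oracle risks are about 0.58 (always control) and 0.38 (always
experimental); censoring at switching underestimates the control-arm risk
by about 0.05, which IPCW (with the correct denominator) and the
g-formula (with generator-faithful models) both remove.

What the generator does *not* emulate: visit-level measurement error,
non-monotone ECOG recovery, informative LTFU, competing risks, or delayed
switching uptake after the decision month. Passing the validation suite
therefore demonstrates correctness of the estimators under the stated
mechanism, not robustness to every real-data pathology.

## Problem sizes and numerical choices

The validation suite runs the confounded-recovery comparison on a
2,000-subject cohort with a 20,000-history oracle and bootstrap standard
errors from 30-60 replicates; the null-recovery check uses 1,000 subjects;
weight-stability checks use a 4,000-subject control arm; the
natural-course audit simulates 20,000 histories against a 2,000-subject
arm. Per-subject RNG streams are derived from `(seed, subject index)`, so
a subject's trajectory is invariant to cohort size and every pipeline is
reproducible from a single integer seed. Logistic fits flag separation
(|coefficient| > 15 or fitted probabilities pinned to 0/1) and
non-convergence honestly; the bootstrap treats either as a replicate
failure. Ratios with zero denominators (zero risk or survival 1 in the
control arm) are flagged undefined rather than returned as infinities.

## Worked example

```{r, eval = FALSE}
library(ppswitch)

cfg <- feedback_config()          # the documented study conditions
trial <- generate_trial(cfg)      # 275 subjects, 48 months

itt <- itt_analysis(trial$table, "unadjusted")
naive <- naive_pp(trial$table, "censor")

sw <- weight_spec("switching",
  denominator = term_list(age = "linear", k = "linear", tls = "linear",
                          ecog_tv = "linear", tdp = "quadratic"))
lt <- weight_spec("ltfu_ac", denominator = term_list(k = "linear"))
ipcw <- ipcw_pp_analysis(trial$table, sw, lt)

spec <- default_gformula_spec()
m0 <- fit_gformula_models(trial$table, spec, arm = 0)
m1 <- fit_gformula_models(trial$table, spec, arm = 1)
gf <- gformula_effects(
  simulate_counterfactual(m0, "always_control", seed = 1),
  simulate_counterfactual(m1, "always_experimental", seed = 2))

truth <- simulate_truth(cfg, "always_control", n_oracle = 20000, seed = 3)
```

## Known limitations

* The stabilized-weight point estimate inherits the eligibility-clock
  approximation discussed above; report it alongside the unstabilized
  estimate when switching is strongly concentrated after a
  subject-specific event.
* The g-formula covariate families cover binary-absorbing, monotone
  ordinal and Gaussian processes; unrestricted categorical covariates and
  non-monotone dynamics require extending the family list.
* Continuous-time Cox partial-likelihood fitting is intentionally absent;
  the discrete hazard ratio is the supported analogue.
* The ad hoc leverage-point weight override sometimes used in applied analyses
  (manually re-setting a handful of extreme weights) is available only as
  explicit truncation; ad hoc per-subject overrides are a user decision,
  not an automatic rule.
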