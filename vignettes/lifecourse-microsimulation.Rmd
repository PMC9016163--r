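---
title: "A discrete-time life-course microsimulation of obesity and type 2 diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discrete-time life-course microsimulation of obesity and type 2 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obesim)
library(data.table)
```

## The model

`obesim` simulates a closed birth cohort — no entry, exit, death, migration
or fertility — nested in neighborhoods and followed through ten discrete
critical life stages, from birth (ages 0–1, stage 0) to middle adulthood
(ages 60–65, stage 9). The default bands are 0–1, 2–5, 6–12, 13–17, 18–24,
25–29, 30–39, 40–49, 50–59 and 60–65 years; at each stage an agent's age is
drawn uniformly within the band. A stage is "adult" when its lower bound is
at least 18.

Each agent carries three attribute domains:

* **socio-demographics** — sex, race (White / non-White), income group
  (below / at-or-above the federal poverty level), and marital status.
  Sex, race and income group are fixed at birth (agents inherit their
  household's group); marriage is possible only from age 18.
* **behaviors** — binary indicators at the thresholds commonly reported in
  population surveys: breastfeeding for six months or more (first year
  only), sugar-sweetened beverage (SSB) consumption above one 12-oz drink
  per day, fast-food consumption more than once per week, at least five
  daily servings of fresh fruit and vegetables (FFV), engagement in
  moderate-to-vigorous physical activity, and — from age 18 — smoking and
  alcohol consumption.
* **outcomes** — continuous BMI (kg/m²), the derived BMI z-score and
  weight status, and type 2 diabetes (T2DM) status, possible only from age
  18 and treated as an absorbing diagnosis.

Neighborhoods carry three domains as well: socio-demographic composition
(proportions non-White, below the poverty level, and with a bachelor's
degree or higher), a physical-activity environment (walkability, park
access), and a food environment (supermarket and fast-food density). The
environment attributes are predicted from the socio-demographic composition
by linear equations with Gaussian noise; densities are clipped at zero.

### Equations and execution order

Every engine-updated variable has one equation per applicable stage: a
linear predictor over named terms with an identity link (continuous
outcomes, plus Gaussian noise) or a logit link (binary outcomes, Bernoulli
draw through the expit function). Terms may be lagged: a lag-1 term reads
the predictor's value at the previous stage. Within a stage the update
order is fixed:

1. **behaviors**, each from its own lag-1 value, socio-demographics, and —
   for diet and activity — neighborhood attributes. Behaviors never depend
   on one another within a stage. The activity equation also includes
   lag-1 BMI with a negative coefficient: the feedback loop by which
   weight gain suppresses subsequent exercise.
2. **BMI**, from lag-1 BMI, the *current* stage's behaviors, and
   socio-demographics.
3. **T2DM** (adult stages), from current BMI, current behaviors, and
   socio-demographics; a prior diagnosis is carried forward unconditionally
   (absorbing). Whether the diabetes equation reads current or lag-1 BMI is
   configurable (`t2dm_bmi_lag`); current BMI is the default.
4. **classification**: agents under 18 are classified by BMI z-score
   (underweight < −2, normal [−2, 1), overweight [1, 2), obese ≥ 2)
   against an LMS growth reference; adults by BMI (underweight < 18.5,
   normal [18.5, 25), overweight [25, 30), obese ≥ 30). The dispatch age is
   18 so the anthropometric rule coincides with the model's adult-stage
   boundary, although child z-score references conventionally extend to
   age 19 — a deliberate simplification.

Obesity is *not* absorbing: BMI is continuous and can fall, and only the
first crossing into the obese category counts as an incident event.

### Initialization

Neighborhoods are initialized first: socio-demographic proportions are
drawn from configurable normal distributions truncated to [0, 1] (defaults:
non-White mean 0.635, poverty 0.175, bachelor's 0.30), then the environment
is predicted. Agents are then created — 418 per neighborhood across 235
neighborhoods, 98,230 in all, by default — with race Bernoulli in the
neighborhood's non-White share, income group Bernoulli in its poverty
share, and sex Bernoulli(0.5) (the sex split is configurable; surveys of
the source region do not pin it down). Stage-0 behaviors and BMI come from
the stage-0 equations, which by construction contain no lagged terms.

## The default parameter set as the study conditions

The shipped configuration (`default_parameter_set()`) is synthetic: the
coefficient tables such a model would estimate from surveys and commercial
establishment data are not redistributable, so the package constructs a
complete, internally consistent set whose *signs* follow the model's causal
structure (SSB and fast food raise BMI; activity lowers it; BMI raises
diabetes risk; lag-1 BMI lowers activity) and whose *marginals* track
stage-specific target trajectories chosen once to match the qualitative
life-course patterns the model is designed around:

* fast food high and declining with age (≈ 0.85 in childhood to 0.55 at
  60–65); SSB likewise (≈ 0.68 to 0.45);
* physical activity low and declining, with its minimum (0.20) in
  adolescence;
* FFV roughly flat around 0.4–0.5; breastfeeding 0.21;
* mean BMI rising from ≈ 16 at birth to ≈ 28.9 at 60–65, with residual
  noise chosen so the adult BMI standard deviation settles near 4.5 and
  adult obesity prevalence climbs from ≈ 18% at 18–24 to ≈ 40% at 60–65;
* T2DM stage hazards of 0.015, 0.05, 0.10, 0.22, 0.18 and 0.15 across the
  six adult stages — below 2% at 18–24, peaking at 40–49 — implying a
  cumulative incidence near 54% by 65.

Intercepts are derived analytically: for each equation,
`intercept = link(target) − Σ coefficient × E[predictor]`, with expected
predictor values taken from the same trajectories (lag-1 terms use the
previous stage's target) and from the neighborhood distribution means. For
logistic equations this first-order correction ignores the nonlinearity of
the expit, so realized proportions sit within a few percentage points of
target; `calibrate()` exists to close that gap. The same trajectories ship
as the default calibration target table, and BMI draws are clipped to
[10, 80] kg/m² to keep the activity feedback biologically plausible.

The growth reference is likewise synthetic (`default_growth_reference()`):
a smooth LMS table over 0–240 months built from spline anchors that mimic
the familiar shape of pediatric BMI references (infant peak, adiposity
rebound near ages 5–6, adolescent rise), with a slight female offset. It is
not a published standard — users can substitute the CDC or WHO table in the
same `sex / age_months / L / M / S` layout.

What the generator does *not* emulate: secular and cohort trends (the
trajectories are pure age profiles), within-stage event timing, social
network transmission, mortality and competing risks, agent relocation, or
household structure. Passing tests therefore demonstrate the mechanics of
the simulator and estimators under known conditions — not empirical
validity for any real population.

## Calibration-in-the-large

Calibration tunes the parameters that cannot be taken from the literature —
intercepts, and optionally feedback coefficients — so that each simulated
stage mean matches its observed target ("calibration-in-the-large"). It
proceeds sequentially from stage 0 to stage 9, freezing earlier stages.
Within a stage, each targeted equation's grid is scored by realizing the
equation on `replicates` parallel cohorts (default 3) that share
*common random numbers* across grid points — the pre-drawn uniforms and
Gaussian residuals are fixed, so grid comparisons are not inflated by
Monte-Carlo noise — and the absolute gap between the replicate-averaged
mean and the target is minimized. Ties go to the smallest coefficient
magnitude. After the coarse pass (41 points) the grid is re-centered on the
optimum with 5× finer spacing (one refinement round by default).

Two numerical choices deserve note:

* **Grid centering.** Intercept grids are centered on the equation's
  *current* intercept (half-width 2 on the logit scale; `2 × max(noise_sd,
  1)` for identity links), not on `link(target)`: with lagged and covariate
  terms, the intercept is offset from `link(target)` by the expected term
  contribution, and centering on `link(target)` can place the optimum
  outside the grid entirely, after which errors compound through the lag
  structure.
* **Identifiability.** An intercept and a feedback coefficient are not
  jointly identified from a single stage mean — raising one and lowering
  the other can reproduce the same marginal. Joint tuning
  (`default_grids(..., tune_feedback = TRUE)`, the default) is therefore a
  calibration device, not an estimator of either parameter; when the aim is
  to recover intercepts from synthetic targets, use intercept-only grids.

Internal validation reports, per variable, the variance explained
(`r_squared()`) between the simulated and observed series across stages;
with fewer than three observed points (breastfeeding, for instance) it is
flagged undefined rather than reported as a number. The per-stage MAE
before and after tuning is returned as a trace; tuning can only improve (or
preserve) it whenever the incumbent value lies on the grid.

## Epidemiologic measures

Measures are computed from the long-format panel for configurable risk
windows — by default whole-span obesity (ages 2–65), childhood obesity
(2–17), adult obesity (18–65), and adult T2DM (18–65):

* **At-risk rule.** Agents positive at the last stage before the window are
  prevalent and excluded. Adult windows therefore *re-enter* agents who
  were obese in childhood but had reverted by 13–17; diabetes, being
  impossible before 18, has everyone at risk.
* **First events and person-time.** The event stage is the first in-window
  stage with positive status; the event age is that stage's band midpoint.
  Events contribute midpoint-minus-entry years; censored agents contribute
  the full window width. The exact accrual rule such tables use is
  generally unstated, so person-time here is validated by its properties
  (bounds, additivity, strict inequality under early events) rather than
  against any published cell.
* **Intervals.** Cumulative incidence (events / at-risk, in percent)
  carries a binomial Wald interval; incidence rates (per 1,000
  person-years) a Poisson Wald interval, `r ± 1.96 × 1000 × √events / py`.
  Both reproduce standard published cohort tables at printed rounding, so
  no score or exact intervals are offered.
* **Age-specific incidence** divides first events at a stage by the count
  entering that stage never having been positive; it is flagged undefined
  (NA with a warning) when no one is at risk. Stage-specific rates divide
  by band person-time, not calendar width.

The measure table reports each window for the whole cohort and by race, and
verifies that stratum totals sum to the overall total.

## Interventions

An intervention overrides one engine variable or neighborhood attribute,
either after the draw (`set`, forcing a value) or through the linear
predictor before it (`shift` adds on the link scale; `multiply` scales one
named coefficient) — both timings are supported because "altering an
exposure to a desired level" can legitimately mean either. Subpopulations
are selected by a filter expression over the working columns. Because `set`
leaves the equation draw in place, a run with and without an intervention
consumes the random stream identically: paired seeds give exact
common-random-number contrasts, and a null intervention contrasts to
exactly zero. `scenario_contrast()` repeats the paired comparison over
replicate seeds (20 by default) to attach Monte-Carlo uncertainty.

## Determinism and problem sizes

One shared random stream per run is consumed in a documented fixed order —
neighborhood draws, agent initialization, then stage-major/variable-major
vectorized draws — so a seed yields a bit-identical panel, and
order-independence claims are testable. Calibration derives its own
per-(replicate, stage, variable) streams from the seed, which is also what
makes target generation and re-calibration exactly pairable.

The full default cohort (98,230 agents × 10 stages) simulates in a few
seconds on one core. The test suite exercises the full-scale run for the
structural and rule checks, a 10,000-agent cohort (25 neighborhoods × 400
agents, 3 replicates) for calibration recovery, and cohorts of a few
hundred to a few thousand agents for unit-level properties — sizes chosen
to keep each property's Monte-Carlo error well below its assertion
tolerance.

## Known limitations

* Coefficients and targets are synthetic stand-ins; absolute outputs of the
  default configuration are illustrative, not forecasts.
* The closed-cohort design overstates incidence and prevalence relative to
  a real population subject to mortality and migration.
* Calibration matches first moments only; distributional shape is inherited
  from the equation forms.
* Behaviors are binary at fixed thresholds; intensity margins (e.g. drinks
  per day) are not modeled.
* The child/adult classification boundary at 18 diverges from the 0–19
  convention of child z-score references by design, as noted above.

## A worked example

```{r example, eval = FALSE}
ps <- default_parameter_set(seed = 1)
sim <- run_simulation(ps, seed = 1)
measure_table(sim$panel, strata = "all")

ps0 <- apply_intervention(ps, intervention_spec("ssb", rule = "set", value = 0))
contrast(sim, run_simulation(ps0, seed = 1))
```
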