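# obesim

Agent-based life-course microsimulation of obesity and type 2 diabetes in
R. `obesim` is aimed at epidemiologists and health-policy modelers who want
a self-contained, reproducible discrete-time cohort simulator: a closed
birth cohort of agents nested in neighborhoods, advanced through ten
critical life stages (birth to ages 60–65), with lagged behavior and
outcome equations, calibration-in-the-large against age-band targets,
cohort incidence measures, and counterfactual intervention scenarios.

## The model in brief

Agents live in neighborhoods whose built and food environments are
predicted from neighborhood socio-demographics. At each life stage *t*,
each agent's binary health behaviors (sugar-sweetened beverages, fast food,
fruit & vegetables, physical activity, and — from age 18 — smoking and
alcohol) are drawn from logistic equations of the form

    logit P(Y_t = 1) = α_t + β·Y_{t−1} + γ'·X + δ'·Z

with socio-demographics *X* and (for diet/activity) neighborhood attributes
*Z*; continuous BMI follows an identity-link equation in lag-1 BMI and the
current behaviors, and type 2 diabetes is a logistic function of current
BMI and behaviors, absorbing once diagnosed. Lag-1 BMI enters the activity
equation with a negative coefficient (weight gain suppresses exercise — the
model's feedback loop). Children are classified by LMS-based BMI z-scores
(obese at z ≥ 2), adults by BMI cutoffs (obese at ≥ 30 kg/m²).

Cohort measures follow standard definitions: cumulative incidence
(first events / at-risk, Wald binomial CI), incidence rates per 1,000
person-years (Poisson CI), age-specific incidence proportions, and
prevalence, overall and by race stratum.

Calibration-in-the-large tunes equation intercepts (and optionally the
feedback coefficients) by sequential per-stage grid search minimizing the
mean absolute error between simulated and observed stage means, with common
random numbers across grid points; internal validation reports per-variable
R² across stages.

The shipped default configuration — 235 neighborhoods × 418 agents =
98,230 agents — is **synthetic**: coefficients are constructed so that signs
follow the causal structure and marginals track documented life-course
trajectories. See the methods vignette
(`vignettes/lifecourse-microsimulation.Rmd`) for every assumption.

## A worked example

```r
library(obesim)

ps  <- default_parameter_set(seed = 1)
sim <- run_simulation(ps, seed = 1)
sim
#> <obesim_sim> seed 1 | 98230 agents x 10 stages = 982300 rows

measure_table(sim$panel, strata = "all")
#>             window total_n events person_years  rate cum_inc
#> 1:  obesity (2-65)   85354  65791      2726462  24.1    77.1
#> 2:  obesity (2-17)   85354  31165      1044162  29.8    36.5
#> 3: obesity (18-65)   75985  49585      2234934  22.2    65.3
#> 4:    t2dm (18-65)   98230  54415      3512639  15.5    55.4
```

Reading the table: of the 85,354 agents not already obese at the first
follow-up stage, 77.1% cross into obesity at least once by age 65, at an
average rate of 24.1 first events per 1,000 person-years; 55.4% of adults
develop type 2 diabetes by 65 (all agents are at risk at 18, since diabetes
cannot occur earlier). `rate_lower`/`rate_upper` and
`cum_lower`/`cum_upper` columns (not shown) carry the 95% Wald intervals.

A counterfactual scenario — eliminating sugar-sweetened beverage
consumption — against the natural course under the same seed (common random
numbers):

```r
ps0 <- apply_intervention(ps, intervention_spec("ssb", rule = "set", value = 0))
contrast(sim, run_simulation(ps0, seed = 1))
#>                 measure           label natural intervention difference
#> 1: cumulative_incidence  obesity (2-65)  77.080       64.182    -12.898
#> 2: cumulative_incidence  obesity (2-17)  36.513       24.960    -11.553
#> 3: cumulative_incidence obesity (18-65)  65.256       53.334    -11.923
#> 4: cumulative_incidence    t2dm (18-65)  55.396       48.247     -7.149
```

Removing SSBs lowers lifetime obesity cumulative incidence by ~13
percentage points and diabetes by ~7 in this configuration, with stage-9
obesity prevalence falling from 39.9% to 29.2%.

Calibration and reporting:

```r
res <- calibrate(ps, default_target_table(), replicates = 3, seed = 1)
res$mae_trace      # per-stage MAE before/after tuning
res$r_squared      # per-variable variance explained across stages
```

A thin command-line front end covering the same workflow (simulate,
calibrate, measure, intervene, report) is installed at
`system.file("cli", "obesim.R", package = "obesim")`.

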