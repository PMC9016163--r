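# Parameter configuration: life-stage schedule, equation specifications,
# parameter sets, calibration target tables, validation and text-file I/O.

#' Life-stage schedule
#'
#' The cohort is advanced through 10 discrete critical life stages. The
#' default bands run from birth (ages 0--1, stage 0) to middle adulthood
#' (ages 60--65, stage 9). A stage is flagged adult when its lower age bound
#' is at least 18.
#'
#' @param age_low,age_high numeric vectors of length 10: the age bands, in
#'   years.
#' @return a `data.table` with columns `stage` (0--9), `age_low`, `age_high`,
#'   `adult`.
#' @examples
#' life_stage_schedule()
#' @export
life_stage_schedule <- function(age_low = c(0, 2, 6, 13, 18, 25, 30, 40, 50, 60),
                                age_high = c(1, 5, 12, 17, 24, 29, 39, 49, 59, 65)) {
  stopifnot(length(age_low) == 10L, length(age_high) == 10L)
  sched <- data.table(stage = 0:9, age_low = as.numeric(age_low),
                      age_high = as.numeric(age_high))
  sched[, adult := age_low >= 18]
  sched[]
}

#' Equation specification
#'
#' One behavior, outcome or neighborhood-environment equation: a linear
#' predictor over named terms with an identity or logit link. Identity-link
#' equations add Gaussian noise with standard deviation `noise_sd`;
#' logit-link equations draw a Bernoulli outcome and must have
#' `noise_sd = 0`. Each term carries a `lag` flag: lag-1 terms read the
#' predictor's value at the previous life stage.
#'
#' @param variable name of the dependent variable.
#' @param stage life-stage index 0--9 for agent equations, `NA` for
#'   neighborhood-environment equations (evaluated once at initialization).
#' @param link `"identity"` or `"logit"`.
#' @param intercept numeric intercept.
#' @param terms `data.table`/data.frame with columns `predictor` (character),
#'   `lag` (0 or 1) and `coefficient` (numeric); may have zero rows.
#' @param noise_sd non-negative residual standard deviation (identity link
#'   only).
#' @param evidence_level provenance tag: `"1"`, `"2"`, `"3"` or
#'   `"synthetic"`.
#' @return an object of class `equation_spec`.
#' @examples
#' equation_spec("bmi", 4, "identity", intercept = 22,
#'               terms = data.frame(predictor = "bmi", lag = 1, coefficient = 0.6),
#'               noise_sd = 3)
#' @export
equation_spec <- function(variable, stage, link = c("identity", "logit"),
                          intercept = 0, terms = NULL, noise_sd = 0,
                          evidence_level = "synthetic") {
  link <- match.arg(link)
  if (is.null(terms)) {
    terms <- data.table(predictor = character(), lag = integer(),
                        coefficient = numeric())
  } else {
    terms <- as.data.table(terms)[, .(predictor = as.character(predictor),
                                      lag = as.integer(lag),
                                      coefficient = as.numeric(coefficient))]
  }
  structure(list(variable = as.character(variable),
                 stage = if (is.na(stage)) NA_integer_ else as.integer(stage),
                 link = link,
                 intercept = as.numeric(intercept),
                 terms = terms,
                 noise_sd = as.numeric(noise_sd),
                 evidence_level = as.character(evidence_level)),
            class = "equation_spec")
}

eq_key <- function(variable, stage) {
  paste0(variable, "@", ifelse(is.na(stage), "env", stage))
}

#' Retrieve an equation from a parameter set
#'
#' @param ps a `parameter_set`.
#' @param variable dependent-variable name.
#' @param stage stage index, or `NA` for environment equations.
#' @return the `equation_spec`, or an error if absent.
#' @export
get_equation <- function(ps, variable, stage = NA) {
  key <- eq_key(variable, stage)
  eq <- ps$equations[[key]]
  if (is.null(eq)) stop("no equation for variable '", variable, "' at stage ",
                        ifelse(is.na(stage), "env", stage))
  eq
}

#' Assemble a parameter set
#'
#' Collects everything one simulation run needs: the life-stage schedule,
#' population structure (neighborhood count and inhabitants per
#' neighborhood), the sampling distributions of neighborhood
#' socio-demographics, all equations (environment, behavior, outcome), the
#' growth reference for child BMI z-scores, and assorted scalars.
#'
#' @param schedule a life-stage schedule.
#' @param n_neighborhoods,agents_per_neighborhood integers; their product is
#'   the cohort size.
#' @param nbhd_dist `data.table` with columns `name`, `mean`, `sd` for the
#'   three neighborhood proportions (`pct_nonwhite`, `pct_below_fpl`,
#'   `pct_bachelor`); draws are truncated to \[0, 1\].
#' @param equations list of [equation_spec()] objects.
#' @param growth_reference LMS growth-reference table (see
#'   [default_growth_reference()]).
#' @param targets optional calibration target table (see
#'   [default_target_table()]).
#' @param sex_prob probability an agent is drawn female.
#' @param bmi_clip length-2 numeric: BMI draws are clipped to this range to
#'   keep the BMI/activity feedback loop biologically plausible.
#' @param t2dm_bmi_lag 0 (default) if the diabetes equation reads
#'   current-stage BMI, 1 for previous-stage BMI.
#' @param seed default random seed stored with the configuration.
#' @return an object of class `parameter_set`.
#' @export
parameter_set <- function(schedule, n_neighborhoods, agents_per_neighborhood,
                          nbhd_dist, equations, growth_reference,
                          targets = NULL, sex_prob = 0.5,
                          bmi_clip = c(10, 80), t2dm_bmi_lag = 0L,
                          seed = 1L) {
  names(equations) <- vapply(equations, function(e) eq_key(e$variable, e$stage), "")
  equations <- equations[order(names(equations))]
  ps <- structure(list(
    schedule = as.data.table(schedule),
    n_neighborhoods = as.integer(n_neighborhoods),
    agents_per_neighborhood = as.integer(agents_per_neighborhood),
    population_size = as.integer(n_neighborhoods) * as.integer(agents_per_neighborhood),
    nbhd_dist = as.data.table(nbhd_dist),
    equations = equations,
    growth_reference = as.data.table(growth_reference),
    targets = if (is.null(targets)) NULL else as.data.table(targets),
    sex_prob = as.numeric(sex_prob),
    bmi_clip = as.numeric(bmi_clip),
    t2dm_bmi_lag = as.integer(t2dm_bmi_lag),
    seed = as.integer(seed),
    interventions = list()
  ), class = "parameter_set")
  ps
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat("  population:", x$n_neighborhoods, "neighborhoods x",
      x$agents_per_neighborhood, "agents =", x$population_size, "agents\n")
  cat("  stages: 10 (ages", x$schedule$age_low[1], "to",
      x$schedule$age_high[10], ")\n")
  cat("  equations:", length(x$equations),
      "| interventions:", length(x$interventions), "\n")
  invisible(x)
}

# ---- default synthetic configuration ---------------------------------------

# Stage-specific marginal trajectories (means for BMI, proportions
# otherwise). These encode the qualitative life-course patterns the model is
# designed around -- high and declining fast-food and sugar-sweetened
# beverage consumption, physical activity lowest in adolescence, roughly one
# in five infants breastfed six months or more, adult BMI drifting upward --
# and double as the default calibration target table.
default_trajectories <- function() {
  traj <- list(
    ssb       = c(0.30, 0.62, 0.68, 0.70, 0.62, 0.58, 0.55, 0.52, 0.48, 0.45),
    fastfood  = c(0.40, 0.78, 0.85, 0.82, 0.75, 0.72, 0.68, 0.64, 0.60, 0.55),
    ffv       = c(0.55, 0.48, 0.42, 0.40, 0.45, 0.47, 0.48, 0.48, 0.49, 0.50),
    activity  = c(0.50, 0.45, 0.40, 0.20, 0.32, 0.30, 0.29, 0.28, 0.26, 0.25),
    bmi       = c(16.0, 15.9, 17.5, 21.5, 26.0, 26.8, 27.6, 28.2, 28.6, 28.9),
    breastfed = c(0.21, rep(NA_real_, 9)),
    smoking   = c(rep(NA_real_, 4), 0.12, 0.15, 0.15, 0.14, 0.12, 0.10),
    alcohol   = c(rep(NA_real_, 4), 0.45, 0.52, 0.50, 0.48, 0.45, 0.40),
    marital   = c(rep(NA_real_, 4), 0.10, 0.30, 0.55, 0.65, 0.68, 0.66)
  )
  # diabetes: per-stage hazards among the at-risk, low in early adulthood and
  # peaking at ages 40--49; the target trajectory is the implied prevalence
  haz <- c(0.015, 0.05, 0.10, 0.22, 0.18, 0.15)
  traj$t2dm_hazard <- c(rep(NA_real_, 4), haz)
  traj$t2dm <- c(rep(NA_real_, 4), 1 - cumprod(1 - haz))
  traj
}

#' Default calibration target table
#'
#' One observed mean (BMI) or proportion (all other variables) per calibrated
#' variable per life stage, matching the marginal trajectories the shipped
#' default parameter set is built around.
#'
#' @return `data.table` with columns `variable`, `stage`, `observed_value`,
#'   `scale` (`"proportion"` or `"continuous"`).
#' @export
default_target_table <- function() {
  traj <- default_trajectories()
  vars <- setdiff(names(traj), "t2dm_hazard")
  tt <- rbindlist(lapply(vars, function(v) {
    data.table(variable = v, stage = 0:9, observed_value = traj[[v]])
  }))
  tt <- tt[!is.na(observed_value)]
  tt[, scale := ifelse(variable == "bmi", "continuous", "proportion")]
  setkey(tt, variable, stage)
  tt[]
}

# expected value of each neighborhood environment attribute implied by the
# environment equations at the mean neighborhood socio-demographics
env_expected_means <- function(env_eqs, nbhd_dist) {
  mu <- setNames(nbhd_dist$mean, nbhd_dist$name)
  setNames(
    vapply(env_eqs, function(eq) {
      eq$intercept + sum(eq$terms$coefficient * mu[eq$terms$predictor])
    }, 0),
    vapply(env_eqs, `[[`, "", "variable")
  )
}

#' Default synthetic parameter set
#'
#' Builds a complete, internally consistent configuration for the default
#' cohort of 235 neighborhoods with 418 inhabitants each (98,230 agents).
#' Coefficient signs follow the model's causal structure: sugar-sweetened
#' beverage and fast-food consumption raise BMI, physical activity lowers
#' it, BMI raises diabetes risk, and previous-stage BMI lowers current
#' physical activity (feedback). Intercepts are derived analytically so that
#' each equation's marginal mean tracks the default target trajectory
#' ([default_target_table()]) to first order; [calibrate()] can tighten the
#' match.
#'
#' @param seed integer stored as the configuration's default run seed;
#'   construction itself is deterministic.
#' @param n_neighborhoods,agents_per_neighborhood population structure
#'   (defaults 235 and 418).
#' @return a validated `parameter_set`.
#' @examples
#' ps <- default_parameter_set(1)
#' ps$population_size  # 98230
#' @export
default_parameter_set <- function(seed = 1L, n_neighborhoods = 235L,
                                  agents_per_neighborhood = 418L) {
  sched <- life_stage_schedule()
  traj <- default_trajectories()
  nbhd_dist <- data.table(
    name = NBHD_SOCIO_VARS,
    mean = c(0.635, 0.175, 0.30),
    sd = c(0.20, 0.08, 0.12)
  )

  term_dt <- function(predictor, lag, coefficient) {
    data.table(predictor = predictor, lag = as.integer(lag),
               coefficient = coefficient)
  }

  # neighborhood built/food environment predicted from socio-demographics
  env_eqs <- list(
    equation_spec("walkability", NA, "identity", 35,
                  term_dt(c("pct_bachelor", "pct_below_fpl"), 0, c(40, -15)), 10),
    equation_spec("park_access", NA, "identity", 1.0,
                  term_dt("pct_bachelor", 0, 2.5), 0.6),
    equation_spec("supermarket_density", NA, "identity", 0.8,
                  term_dt(c("pct_bachelor", "pct_below_fpl"), 0, c(1.5, -0.6)), 0.3),
    equation_spec("fastfood_density", NA, "identity", 0.8,
                  term_dt("pct_below_fpl", 0, 2.5), 0.4)
  )
  env_mu <- env_expected_means(env_eqs, nbhd_dist)

  # predictor means used for the analytic intercepts
  mu <- c(sex = 0.5, race = nbhd_dist$mean[1], ses_group = nbhd_dist$mean[2],
          env_mu)
  tv <- function(v, t) traj[[v]][t + 1L]   # trajectory value at stage t
  logit <- function(p) log(p / (1 - p))

  # behavior equation skeletons: socio-demographic terms everywhere,
  # neighborhood terms in diet/activity, lag-1 self-persistence after birth,
  # lag-1 BMI feedback in the activity equation
  beh_terms <- list(
    ssb = term_dt(c("sex", "race", "ses_group", "fastfood_density"), 0,
                  c(-0.10, 0.25, 0.20, 0.15)),
    fastfood = term_dt(c("sex", "race", "ses_group", "fastfood_density"), 0,
                       c(-0.05, -0.20, 0.15, 0.25)),
    ffv = term_dt(c("sex", "race", "ses_group", "supermarket_density"), 0,
                  c(0.15, -0.15, -0.20, 0.25)),
    activity = term_dt(c("sex", "race", "ses_group", "walkability", "park_access"), 0,
                       c(-0.20, -0.25, -0.15, 0.01, 0.15)),
    smoking = term_dt(c("sex", "race", "ses_group"), 0, c(-0.15, 0.10, 0.40)),
    alcohol = term_dt(c("sex", "race", "ses_group"), 0, c(-0.10, -0.20, -0.10)),
    breastfed = term_dt(c("race", "ses_group"), 0, c(-0.20, -0.25))
  )
  lag_self_coef <- c(ssb = 1.2, fastfood = 1.2, ffv = 1.0, activity = 1.2,
                     smoking = 1.5, alcohol = 1.5)
  activity_bmi_feedback <- -0.04

  eqs <- env_eqs
  add <- function(eq) eqs[[length(eqs) + 1L]] <<- eq

  for (v in c("breastfed", "ssb", "fastfood", "ffv", "activity", "smoking",
              "alcohol", "marital")) {
    for (t in applicable_stages(v, sched)) {
      terms <- if (v == "marital") term_dt(character(), integer(), numeric())
               else copy(beh_terms[[v]])
      # lag-1 self term only where the variable exists at the prior stage
      has_lag <- t > 0 && v %in% names(lag_self_coef) &&
        (t - 1L) %in% applicable_stages(v, sched)
      if (has_lag) terms <- rbind(terms, term_dt(v, 1, lag_self_coef[[v]]))
      if (v == "activity" && t > 0)
        terms <- rbind(terms, term_dt("bmi", 1, activity_bmi_feedback))
      # analytic intercept: marginal target minus expected term contribution
      contrib <- sum(terms[lag == 0, coefficient] *
                       mu[terms[lag == 0, predictor]])
      if (has_lag) contrib <- contrib + lag_self_coef[[v]] * tv(v, t - 1L)
      if (v == "activity" && t > 0)
        contrib <- contrib + activity_bmi_feedback * tv("bmi", t - 1L)
      add(equation_spec(v, t, "logit", logit(tv(v, t)) - contrib, terms))
    }
  }

  # BMI: lagged BMI plus current-stage behaviors and socio-demographics
  bmi_lag <- c(NA, 0.55, 0.55, 0.55, 0.45, 0.65, 0.65, 0.65, 0.65, 0.65)
  bmi_noise <- c(2.0, 2.0, 3.0, 3.2, 4.0, 3.3, 3.3, 3.3, 3.2, 3.1)
  bmi_beh <- c(ssb = 0.9, fastfood = 0.7, ffv = -0.5, activity = -1.0)
  bmi_soc <- c(sex = -0.3, race = 0.5, ses_group = 0.4)
  for (t in 0:9) {
    terms <- rbind(term_dt(names(bmi_beh), 0, unname(bmi_beh)),
                   term_dt(names(bmi_soc), 0, unname(bmi_soc)))
    if (t == 0) terms <- rbind(terms, term_dt("breastfed", 0, -0.3))
    if (t > 0) terms <- rbind(terms, term_dt("bmi", 1, bmi_lag[t + 1L]))
    contrib <- sum(bmi_beh * vapply(names(bmi_beh), tv, 0, t = t)) +
      sum(bmi_soc * mu[names(bmi_soc)]) +
      (if (t == 0) -0.3 * tv("breastfed", 0) else 0) +
      (if (t > 0) bmi_lag[t + 1L] * tv("bmi", t - 1L) else 0)
    add(equation_spec("bmi", t, "identity", tv("bmi", t) - contrib,
                      terms, bmi_noise[t + 1L]))
  }

  # T2DM: logistic hazard on current BMI, behaviors, socio-demographics;
  # the absorbing rule is applied by the engine, not the equation
  t2dm_terms0 <- term_dt(c("race", "ses_group", "activity", "ssb"), 0,
                         c(0.45, 0.30, -0.30, 0.20))
  for (t in applicable_stages("t2dm", sched)) {
    h <- traj$t2dm_hazard[t + 1L]
    terms <- rbind(t2dm_terms0, term_dt("bmi", 0, 0.10))
    contrib <- sum(t2dm_terms0$coefficient *
                     c(mu["race"], mu["ses_group"], tv("activity", t), tv("ssb", t))) +
      0.10 * tv("bmi", t)
    add(equation_spec("t2dm", t, "logit", logit(h) - contrib, terms))
  }

  ps <- parameter_set(sched, n_neighborhoods, agents_per_neighborhood,
                      nbhd_dist, eqs, default_growth_reference(),
                      targets = default_target_table(), seed = seed)
  viol <- validate_parameter_set(ps)
  if (length(viol)) stop("default parameter set invalid: ",
                         paste(viol, collapse = "; "))
  ps
}

# ---- validation -------------------------------------------------------------

#' Validate a parameter set
#'
#' Checks every structural invariant: schedule shape, link/noise rules,
#' lag legality (no lagged terms at birth; every lag-1 predictor defined at
#' the prior stage), adult-only variables restricted to adult stages, exactly
#' one equation per engine-updated variable per applicable stage, population
#' arithmetic, proportion ranges, growth-reference sanity, and (when a target
#' table is attached) target-table invariants.
#'
#' @param ps a `parameter_set`.
#' @return character vector of violation descriptions; empty when valid.
#' @export
validate_parameter_set <- function(ps) {
  v <- character()
  say <- function(...) v <<- c(v, paste0(...))

  sch <- ps$schedule
  if (nrow(sch) != 10L) say("schedule: expected exactly 10 stages, got ", nrow(sch))
  if (nrow(sch) == 10L) {
    if (sch$age_low[1] != 0 || sch$age_high[1] != 1)
      say("schedule: stage 0 must span ages 0-1")
    if (sch$age_low[10] != 60 || sch$age_high[10] != 65)
      say("schedule: stage 9 must span ages 60-65")
    if (any(diff(sch$age_low) <= 0) || any(sch$age_high < sch$age_low) ||
        any(head(sch$age_high, -1) > tail(sch$age_low, -1)))
      say("schedule: age bands must be increasing and non-overlapping")
  }

  if (ps$n_neighborhoods < 1L || ps$agents_per_neighborhood < 1L)
    say("population: neighborhood and agent counts must be positive")
  if (ps$population_size != ps$n_neighborhoods * ps$agents_per_neighborhood)
    say("population: declared size ", ps$population_size,
        " != n_neighborhoods x agents_per_neighborhood")

  if (!setequal(ps$nbhd_dist$name, NBHD_SOCIO_VARS))
    say("nbhd_dist: must contain exactly ", paste(NBHD_SOCIO_VARS, collapse = ", "))
  bad <- ps$nbhd_dist[mean < 0 | mean > 1 | sd < 0]
  for (nm in bad$name)
    say("nbhd_dist: ", nm, " mean must lie in [0,1] and sd be non-negative")

  known_predictors <- c(SOCIODEM_VARS, NBHD_SOCIO_VARS, ENV_VARS, ENGINE_VARS)
  for (eq in ps$equations) {
    where <- paste0(eq$variable, "@", ifelse(is.na(eq$stage), "env", eq$stage))
    if (!eq$link %in% c("identity", "logit"))
      say(where, ": unknown link '", eq$link, "'")
    if (eq$noise_sd < 0) say(where, ": noise_sd must be >= 0")
    if (eq$link == "logit" && eq$noise_sd != 0)
      say(where, ": logit-link equations must have noise_sd = 0")
    unknown <- setdiff(eq$terms$predictor, known_predictors)
    for (p in unknown) say(where, ": unknown predictor '", p, "'")
    if (!is.na(eq$stage)) {
      if (eq$stage == 0L && any(eq$terms$lag == 1L))
        say(where, ": lagged terms are not allowed at stage 0 (birth)")
      if (eq$variable %in% ADULT_ONLY_VARS && nrow(sch) == 10L &&
          eq$stage %in% sch[adult == FALSE, stage])
        say(where, ": ", eq$variable,
            " is adult-only (18+) but has an equation at a child stage")
      lagged <- eq$terms[lag == 1L, predictor]
      for (p in intersect(lagged, ENGINE_VARS)) {
        if (!(eq$stage - 1L) %in% applicable_stages(p, sch))
          say(where, ": lag-1 predictor '", p, "' does not exist at stage ",
              eq$stage - 1L)
      }
      for (p in setdiff(lagged, ENGINE_VARS))
        say(where, ": lag-1 term on time-invariant predictor '", p, "'")
    } else {
      if (!eq$variable %in% ENV_VARS)
        say(where, ": stage-free equations are reserved for environment attributes")
      if (length(setdiff(eq$terms$predictor, NBHD_SOCIO_VARS)))
        say(where, ": environment equations may only use neighborhood socio-demographics")
    }
  }

  # schema completeness: exactly one equation per applicable (variable, stage)
  if (nrow(sch) == 10L) {
    keys <- names(ps$equations)
    for (vv in ENGINE_VARS) {
      for (t in applicable_stages(vv, sch)) {
        k <- eq_key(vv, t)
        n <- sum(keys == k)
        if (n == 0L) say("missing equation for '", vv, "' at stage ", t)
        if (n > 1L) say("duplicate equations for '", vv, "' at stage ", t)
      }
      extra <- grep(paste0("^", vv, "@"), keys, value = TRUE)
      extra_stages <- suppressWarnings(as.integer(sub(".*@", "", extra)))
      bad_t <- setdiff(extra_stages[!is.na(extra_stages)],
                       applicable_stages(vv, sch))
      for (t in bad_t) say("equation for '", vv, "' at inapplicable stage ", t)
    }
    for (vv in ENV_VARS)
      if (!eq_key(vv, NA) %in% keys) say("missing environment equation for '", vv, "'")
  }

  gr <- ps$growth_reference
  if (!all(c("sex", "age_months", "L", "M", "S") %in% names(gr))) {
    say("growth_reference: must have columns sex, age_months, L, M, S")
  } else {
    if (any(gr$M <= 0) || any(gr$S <= 0))
      say("growth_reference: M and S must be positive")
    for (s in unique(gr$sex)) {
      a <- gr[sex == s, age_months]
      if (any(diff(a) <= 0))
        say("growth_reference: ages must be strictly increasing within sex ", s)
      if (min(a) > 24 || max(a) < 240)
        say("growth_reference: sex ", s, " must cover at least 24-240 months")
    }
  }

  if (length(ps$bmi_clip) != 2L || ps$bmi_clip[1] >= ps$bmi_clip[2] ||
      ps$bmi_clip[1] <= 0)
    say("bmi_clip: must be an increasing positive range")
  if (ps$sex_prob < 0 || ps$sex_prob > 1) say("sex_prob: must lie in [0,1]")

  if (!is.null(ps$targets)) v <- c(v, validate_target_table(ps$targets))
  v
}

#' Validate a calibration target table
#'
#' @param targets `data.table` with columns `variable`, `stage`,
#'   `observed_value`, `scale`.
#' @return character vector of violation descriptions; empty when valid.
#' @export
validate_target_table <- function(targets) {
  v <- character()
  targets <- as.data.table(targets)
  need <- c("variable", "stage", "observed_value", "scale")
  if (!all(need %in% names(targets)))
    return(paste0("target table: must have columns ", paste(need, collapse = ", ")))
  bad <- targets[scale == "proportion" & (observed_value < 0 | observed_value > 1)]
  for (i in seq_len(nrow(bad)))
    v <- c(v, paste0("target table: proportion target for '", bad$variable[i],
                     "' at stage ", bad$stage[i], " (", bad$observed_value[i],
                     ") outside [0,1]"))
  dup <- targets[, .N, by = .(variable, stage)][N > 1L]
  for (i in seq_len(nrow(dup)))
    v <- c(v, paste0("target table: duplicate rows for '", dup$variable[i],
                     "' at stage ", dup$stage[i]))
  if (!all(targets$scale %in% c("proportion", "continuous")))
    v <- c(v, "target table: scale must be 'proportion' or 'continuous'")
  v
}

# ---- text-file I/O ----------------------------------------------------------

fmt_num <- function(x) sprintf("%.17g", x)

write_tsv17 <- function(dt, path) {
  dt <- copy(as.data.table(dt))
  for (cl in names(dt)) if (is.numeric(dt[[cl]]))
    set(dt, j = cl, value = ifelse(is.na(dt[[cl]]), NA_character_, fmt_num(dt[[cl]])))
  fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
}

equations_to_tables <- function(equations) {
  meta <- rbindlist(lapply(equations, function(eq) {
    data.table(variable = eq$variable, stage = eq$stage, link = eq$link,
               noise_sd = eq$noise_sd, evidence_level = eq$evidence_level)
  }))
  coefs <- rbindlist(lapply(equations, function(eq) {
    rows <- rbind(
      data.table(predictor = "(Intercept)", lag = 0L, coefficient = eq$intercept),
      eq$terms[, .(predictor, lag, coefficient)]
    )
    data.table(variable = eq$variable, stage = eq$stage, rows,
               evidence_level = eq$evidence_level)
  }))
  list(meta = meta, coefficients = coefs)
}

tables_to_equations <- function(meta, coefs) {
  meta <- as.data.table(meta); coefs <- as.data.table(coefs)
  lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i]
    rows <- coefs[variable == m$variable &
                    ((is.na(stage) & is.na(m$stage)) |
                       (!is.na(stage) & !is.na(m$stage) & stage == m$stage))]
    int <- rows[predictor == "(Intercept)", coefficient]
    equation_spec(m$variable, m$stage, m$link, intercept = int,
                  terms = rows[predictor != "(Intercept)",
                               .(predictor, lag, coefficient)],
                  noise_sd = m$noise_sd, evidence_level = m$evidence_level)
  })
}

#' Write a parameter set to a configuration directory
#'
#' Writes a human-readable configuration: `config.yml` for scalar structure,
#' tab-separated tables for the schedule, neighborhood distributions,
#' equation metadata, the coefficient table (`variable`, `stage`,
#' `predictor`, `lag`, `coefficient`, `evidence_level`; the intercept is the
#' `(Intercept)` row), the growth reference, and the calibration targets.
#' Numeric values are written with full double precision so that
#' [load_parameter_set()] round-trips exactly.
#'
#' @param ps a `parameter_set`.
#' @param dir directory to create/write into.
#' @return `dir`, invisibly.
#' @export
save_parameter_set <- function(ps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(n_neighborhoods = ps$n_neighborhoods,
              agents_per_neighborhood = ps$agents_per_neighborhood,
              population_size = ps$population_size,
              sex_prob = fmt_num(ps$sex_prob),
              bmi_clip = fmt_num(ps$bmi_clip),
              t2dm_bmi_lag = ps$t2dm_bmi_lag,
              seed = ps$seed)
  yaml::write_yaml(cfg, file.path(dir, "config.yml"))
  write_tsv17(ps$schedule, file.path(dir, "schedule.tsv"))
  write_tsv17(ps$nbhd_dist, file.path(dir, "neighborhood_distributions.tsv"))
  tabs <- equations_to_tables(ps$equations)
  write_tsv17(tabs$meta, file.path(dir, "equations.tsv"))
  write_tsv17(tabs$coefficients, file.path(dir, "coefficients.tsv"))
  write_tsv17(ps$growth_reference, file.path(dir, "growth_reference.tsv"))
  if (!is.null(ps$targets))
    write_tsv17(ps$targets, file.path(dir, "targets.tsv"))
  invisible(dir)
}

#' Load a parameter set from a configuration directory
#'
#' Reads the layout written by [save_parameter_set()] and validates it;
#' loading fails atomically, naming every violated invariant, if the
#' configuration is inconsistent (e.g. a diabetes equation at a child stage,
#' a lagged term at birth, or a missing equation for an applicable stage).
#'
#' @param path configuration directory.
#' @return a validated `parameter_set`.
#' @export
load_parameter_set <- function(path) {
  if (!dir.exists(path)) stop("configuration directory not found: ", path)
  cfg <- yaml::read_yaml(file.path(path, "config.yml"))
  rd <- function(f) fread(file.path(path, f), sep = "\t", na.strings = "NA")
  sched <- rd("schedule.tsv")
  sched[, `:=`(stage = as.integer(stage), adult = as.logical(adult))]
  meta <- rd("equations.tsv")
  meta[, stage := as.integer(stage)]
  coefs <- rd("coefficients.tsv")
  coefs[, `:=`(stage = as.integer(stage), lag = as.integer(lag))]
  targets_path <- file.path(path, "targets.tsv")
  targets <- if (file.exists(targets_path)) rd("targets.tsv") else NULL
  if (!is.null(targets)) targets[, stage := as.integer(stage)]
  ps <- parameter_set(
    schedule = sched,
    n_neighborhoods = cfg$n_neighborhoods,
    agents_per_neighborhood = cfg$agents_per_neighborhood,
    nbhd_dist = rd("neighborhood_distributions.tsv"),
    equations = tables_to_equations(meta, coefs),
    growth_reference = rd("growth_reference.tsv"),
    targets = targets,
    sex_prob = as.numeric(cfg$sex_prob),
    bmi_clip = as.numeric(cfg$bmi_clip),
    t2dm_bmi_lag = cfg$t2dm_bmi_lag,
    seed = cfg$seed
  )
  if (!is.null(cfg$population_size) &&
      cfg$population_size != ps$n_neighborhoods * ps$agents_per_neighborhood)
    stop("invalid configuration: declared population_size ",
         cfg$population_size, " != n_neighborhoods x agents_per_neighborhood")
  viol <- validate_parameter_set(ps)
  if (length(viol))
    stop("invalid configuration:\n  - ", paste(viol, collapse = "\n  - "))
  ps
}
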