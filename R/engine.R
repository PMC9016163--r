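# Simulation engine: advances the cohort through stages 1-9 by evaluating
# behavior equations (from lagged state), then BMI, then T2DM, per stage,
# with prior-BMI feedback on activity and absorbing diabetes.

#' Inverse-logit (expit) function
#'
#' @param x numeric linear predictor.
#' @return probabilities `1 / (1 + exp(-x))` in (0, 1).
#' @examples
#' expit(0)  # 0.5
#' @export
expit <- function(x) 1 / (1 + exp(-x))

# linear predictor of an equation over a data table; lag-1 terms read
# "lag_<predictor>" columns
linear_predictor <- function(spec, data) {
  lp <- rep(spec$intercept, nrow(data))
  tm <- spec$terms
  for (i in seq_len(nrow(tm))) {
    nm <- if (tm$lag[i] == 1L) paste0("lag_", tm$predictor[i]) else tm$predictor[i]
    val <- data[[nm]]
    if (is.null(val))
      stop("predictor '", tm$predictor[i], "' (lag ", tm$lag[i],
           ") missing for equation ", spec$variable)
    lp <- lp + tm$coefficient[i] * val
  }
  lp
}

#' Evaluate one equation on agent (or neighborhood) data
#'
#' Identity link: returns `intercept + sum(coef * value) + N(0, noise_sd)`.
#' Logit link: returns a Bernoulli draw with probability
#' `expit(linear predictor)`, realized as `runif(n) < p` so that paired runs
#' sharing a random stream are monotonically coupled.
#'
#' @param spec an [equation_spec()].
#' @param input data.frame/data.table holding every predictor the equation
#'   names; lag-1 predictors as `lag_<name>` columns.
#' @param offset optional additive adjustment to the linear predictor.
#' @return numeric vector (identity) or integer 0/1 vector (logit).
#' @export
evaluate_equation <- function(spec, input, offset = 0) {
  input <- as.data.table(input)
  lp <- linear_predictor(spec, input) + offset
  n <- nrow(input)
  if (spec$link == "logit") {
    as.integer(runif(n) < expit(lp))
  } else {
    if (spec$noise_sd > 0) lp + rnorm(n, 0, spec$noise_sd) else lp
  }
}

# evaluate all engine variables for one stage on the working table `cur`
# (numeric race, sociodemographics, environment attributes, age and -- for
# t > 0 -- lag_<var> columns already present); fixed evaluation order:
# behaviors, then BMI, then T2DM, then anthropometric classification
simulate_stage_variables <- function(cur, ps, t) {
  n <- nrow(cur)
  for (v in ENGINE_VARS) {
    if (t %in% applicable_stages(v, ps$schedule)) {
      spec <- get_equation(ps, v, t)
      if (v == "t2dm" && ps$t2dm_bmi_lag == 1L && !is.null(cur[["lag_bmi"]])) {
        spec$terms <- copy(spec$terms)[predictor == "bmi", lag := 1L]
      }
      offset <- rep(0, n)
      sets <- list()
      for (iv in active_interventions(ps, v, t)) {
        mask <- intervention_mask(iv, cur)
        if (iv$rule == "shift") {
          offset[mask] <- offset[mask] + iv$value
        } else if (iv$rule == "multiply") {
          i <- which(spec$terms$predictor == iv$predictor)
          if (length(i)) {
            x <- cur[[if (spec$terms$lag[i[1]] == 1L)
              paste0("lag_", iv$predictor) else iv$predictor]]
            offset[mask] <- offset[mask] +
              (iv$value - 1) * spec$terms$coefficient[i[1]] * x[mask]
          }
        } else {
          sets[[length(sets) + 1L]] <- iv
        }
      }
      val <- evaluate_equation(spec, cur, offset)
      if (v == "bmi") val <- pmin(ps$bmi_clip[2], pmax(ps$bmi_clip[1], val))
      if (v == "t2dm" && !is.null(cur[["lag_t2dm"]]))
        val <- pmax(val, cur[["lag_t2dm"]])  # diagnosis is absorbing
      for (iv in sets) val[intervention_mask(iv, cur)] <- iv$value
      if (spec$link == "logit") val <- as.integer(val)
      set(cur, j = v, value = val)
    } else {
      set(cur, j = v, value = if (v == "bmi") NA_real_ else 0L)
    }
  }
  child <- cur$age < 18
  z <- rep(NA_real_, n)
  if (any(child))
    z[child] <- bmi_zscore(cur$bmi[child],
                           ifelse(cur$sex[child] == 1L, "female", "male"),
                           cur$age[child], ps$growth_reference)
  set(cur, j = "bmi_z", value = z)
  set(cur, j = "weight_status", value = classify_weight(cur$age, cur$bmi, z))
  cur
}

# working table -> public panel rows (factor race, canonical column order)
finalize_panel_rows <- function(cur) {
  out <- cur[, .(agent_id, neighborhood_id, stage, age, sex,
                 race = factor(RACE_LEVELS[race + 1L], levels = RACE_LEVELS),
                 ses_group, marital, breastfed, ssb, fastfood, ffv, activity,
                 smoking, alcohol, bmi, bmi_z, weight_status, t2dm)]
  out
}

#' Advance the cohort by one life stage
#'
#' Builds the stage-`t` working state from the stage-`t-1` rows (lagged
#' behaviors, BMI and diabetes status; time-invariant socio-demographics and
#' neighborhood attributes), draws ages uniformly within the stage band, and
#' evaluates the stage's equations in order: behaviors (from lag-1 state,
#' with lag-1 BMI feeding back on activity), then BMI (lag-1 BMI plus
#' current behaviors), then T2DM (current BMI and behaviors; absorbing),
#' then weight-status classification.
#'
#' @param panel_prev stage `t-1` panel rows.
#' @param neighborhoods output of [build_neighborhoods()].
#' @param ps a `parameter_set`.
#' @param t target stage index, 1--9.
#' @return stage-`t` panel rows.
#' @export
step <- function(panel_prev, neighborhoods, ps, t) {
  stopifnot(t >= 1L, t <= 9L)
  prev <- as.data.table(panel_prev)
  stopifnot(all(prev$stage == t - 1L))
  n <- nrow(prev)
  cur <- data.table(agent_id = prev$agent_id,
                    neighborhood_id = prev$neighborhood_id,
                    sex = prev$sex,
                    race = as.integer(prev$race == "non-White"),
                    ses_group = prev$ses_group,
                    stage = t)
  for (v in c(ENGINE_VARS))
    set(cur, j = paste0("lag_", v), value = prev[[v]])
  cur <- merge(cur, as.data.table(neighborhoods), by.x = "neighborhood_id",
               by.y = "id", sort = FALSE)
  setorder(cur, agent_id)
  cur[, age := draw_age(t, ps$schedule, n)]
  cur <- simulate_stage_variables(cur, ps, t)
  finalize_panel_rows(cur)
}

#' Run a full life-course simulation
#'
#' Seeds the random stream, synthesizes neighborhoods and the birth cohort,
#' and advances all agents through stages 1--9. One shared random stream is
#' consumed in a fixed, documented order (neighborhood draws, agent
#' initialization, then stage-major/variable-major vectorized draws), so a
#' given seed yields a bit-identical panel.
#'
#' @param ps a `parameter_set`.
#' @param seed integer seed (default: the seed stored in `ps`).
#' @return an object of class `obesim_sim`: a list with `panel` (long-format
#'   `data.table`, one row per agent per stage, with the schedule attached
#'   as attribute `"schedule"`), `neighborhoods`, and `log` (seed, per-stage
#'   timings and per-stage variable means).
#' @examples
#' ps <- default_parameter_set(1, n_neighborhoods = 4, agents_per_neighborhood = 25)
#' sim <- run_simulation(ps, seed = 1)
#' nrow(sim$panel)  # 100 agents x 10 stages
#' @export
run_simulation <- function(ps, seed = ps$seed) {
  set.seed(seed)
  timings <- numeric(10)
  t0 <- proc.time()[["elapsed"]]
  nb <- build_neighborhoods(ps)
  rows <- vector("list", 10)
  rows[[1]] <- build_agents(nb, ps)
  timings[1] <- proc.time()[["elapsed"]] - t0
  for (t in 1:9) {
    t0 <- proc.time()[["elapsed"]]
    rows[[t + 1]] <- step(rows[[t]], nb, ps, t)
    timings[t + 1] <- proc.time()[["elapsed"]] - t0
  }
  panel <- rbindlist(rows)
  setattr(panel, "schedule", copy(ps$schedule))
  means <- panel[, c(lapply(.SD, mean), .(obesity = mean(weight_status == "obese"))),
                 by = stage,
                 .SDcols = c("age", "ssb", "fastfood", "ffv", "activity",
                             "smoking", "alcohol", "bmi", "t2dm")]
  structure(list(panel = panel, neighborhoods = nb,
                 log = list(seed = seed,
                            timings = data.table(stage = 0:9, seconds = timings),
                            stage_means = means)),
            class = "obesim_sim")
}

#' @export
print.obesim_sim <- function(x, ...) {
  cat("<obesim_sim> seed", x$log$seed, "|",
      uniqueN(x$panel$agent_id), "agents x",
      uniqueN(x$panel$stage), "stages =", nrow(x$panel), "rows\n")
  invisible(x)
}
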