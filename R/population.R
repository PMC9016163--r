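# Population synthesis: neighborhoods first (socio-demographics drawn, built
# and food environment predicted from them), then the stage-0 agent cohort
# nested within neighborhoods.

#' Synthesize neighborhoods
#'
#' Draws each neighborhood's socio-demographic composition (proportion
#' non-White, proportion below the federal poverty level, proportion with a
#' bachelor's degree or higher) from the configured normal distributions,
#' truncated to \[0, 1\], then predicts the activity and food environment
#' attributes from them via [predict_environment()]. Consumes the current
#' R random stream; call `set.seed()` first for reproducibility.
#'
#' @param ps a `parameter_set`.
#' @return `data.table` with one row per neighborhood: `id`, the three
#'   socio-demographic proportions, `walkability`, `park_access`,
#'   `supermarket_density`, `fastfood_density`.
#' @export
build_neighborhoods <- function(ps) {
  n <- ps$n_neighborhoods
  socio <- data.table(id = seq_len(n))
  for (v in NBHD_SOCIO_VARS) {
    d <- ps$nbhd_dist[name == v]
    socio[, (v) := pmin(1, pmax(0, rnorm(n, d$mean, d$sd)))]
  }
  env <- predict_environment(socio, ps)
  cbind(socio, env)
}

#' Predict neighborhood environment attributes
#'
#' Evaluates the four environment equations (identity link plus Gaussian
#' noise) on neighborhood socio-demographics. Densities are clipped at zero.
#' Scenario interventions targeting environment attributes are applied here
#' (`set` replaces, `shift` adds, `multiply` scales the drawn value, before
#' clipping).
#'
#' @param socio `data.table` of neighborhood socio-demographic proportions.
#' @param ps a `parameter_set`.
#' @return `data.table` of environment attributes, rows aligned with
#'   `socio`.
#' @export
predict_environment <- function(socio, ps) {
  socio <- as.data.table(socio)
  stopifnot(all(vapply(NBHD_SOCIO_VARS, function(v)
    all(socio[[v]] >= 0 & socio[[v]] <= 1), TRUE)))
  n <- nrow(socio)
  env <- data.table(.rows = seq_len(n))
  for (v in ENV_VARS) {
    eq <- get_equation(ps, v, NA)
    val <- evaluate_equation(eq, socio)
    for (iv in active_interventions(ps, v, stage = NA)) {
      mask <- intervention_mask(iv, socio)
      val[mask] <- switch(iv$rule,
                          set = iv$value,
                          shift = val[mask] + iv$value,
                          multiply = val[mask] * iv$value)
    }
    if (v %in% c("supermarket_density", "fastfood_density")) val <- pmax(0, val)
    env[, (v) := val]
  }
  env[, .rows := NULL]
  env[]
}

#' Draw an age within a life stage
#'
#' Ages are uniform within the stage's band.
#'
#' @param stage stage index 0--9.
#' @param schedule a life-stage schedule.
#' @param n number of draws.
#' @return numeric age(s) in years.
#' @export
draw_age <- function(stage, schedule, n = 1L) {
  if (length(stage) != 1L || !stage %in% schedule$stage)
    stop("stage out of range: ", stage)
  i <- match(stage, schedule$stage)
  runif(n, schedule$age_low[i], schedule$age_high[i])
}

#' Initialize the stage-0 agent cohort
#'
#' Creates `agents_per_neighborhood` agents in each neighborhood. Race is
#' Bernoulli in the neighborhood's non-White proportion, the income group
#' Bernoulli in its below-poverty proportion, sex Bernoulli in
#' `ps$sex_prob`, and age uniform on the birth stage's band. Stage-0
#' behaviors and BMI are then drawn from the stage-0 equations (which have
#' no lagged terms); marriage, smoking, alcohol and diabetes start at 0.
#'
#' @param neighborhoods output of [build_neighborhoods()].
#' @param ps a `parameter_set`.
#' @return stage-0 panel rows (one per agent) in the standard panel layout.
#' @export
build_agents <- function(neighborhoods, ps) {
  neighborhoods <- as.data.table(neighborhoods)
  m <- ps$agents_per_neighborhood
  n <- nrow(neighborhoods) * m
  cur <- data.table(agent_id = seq_len(n),
                    neighborhood_id = rep(neighborhoods$id, each = m))
  cur <- merge(cur, neighborhoods, by.x = "neighborhood_id", by.y = "id",
               sort = FALSE)
  setorder(cur, agent_id)
  # fixed draw order: race, income group, sex, age, then stage-0 equations
  cur[, race := as.integer(runif(n) < pct_nonwhite)]
  cur[, ses_group := as.integer(runif(n) < pct_below_fpl)]
  cur[, sex := as.integer(runif(n) < ps$sex_prob)]
  cur[, stage := 0L]
  cur[, age := draw_age(0L, ps$schedule, n)]
  cur <- simulate_stage_variables(cur, ps, 0L)
  finalize_panel_rows(cur)
}
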