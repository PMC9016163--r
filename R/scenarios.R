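# Counterfactual intervention scenarios: override exposures during the run
# and contrast outcome measures against the natural course under common
# random numbers.

#' Define an intervention
#'
#' An intervention overrides one engine-updated agent variable or one
#' neighborhood environment attribute, either after the equation draw
#' (`set`: force a value) or through the linear predictor before the draw
#' (`shift`: add to the linear predictor, i.e. a probability shift on the
#' link scale for logistic variables; `multiply`: scale the coefficient of
#' one named predictor). Because `set` interventions leave the equation draw
#' in place, a run with and without the intervention consumes the random
#' stream identically, so paired seeds give exact common-random-numbers
#' contrasts.
#'
#' @param variable target variable: one of the engine-updated agent
#'   variables or a neighborhood environment attribute.
#' @param stages integer stages affected (`NULL` = all applicable; ignored
#'   for neighborhood attributes, which are set at initialization).
#' @param rule `"set"`, `"shift"` or `"multiply"`.
#' @param value the forced value (`set`), linear-predictor increment
#'   (`shift`), or coefficient multiplier (`multiply`).
#' @param predictor for `multiply`: name of the predictor whose coefficient
#'   is scaled.
#' @param filter optional subpopulation filter: a one-line R expression
#'   (character) over the working columns, e.g. `"ses_group == 1"` or
#'   `"race == 1"` (race is coded 0 = White, 1 = non-White in filters) or,
#'   for neighborhood targets, `"pct_below_fpl > 0.3"`.
#' @return an object of class `intervention_spec`.
#' @examples
#' intervention_spec("ssb", rule = "set", value = 0)
#' @export
intervention_spec <- function(variable, stages = NULL,
                              rule = c("set", "shift", "multiply"),
                              value, predictor = NULL, filter = NULL) {
  rule <- match.arg(rule)
  if (rule == "multiply" && is.null(predictor))
    stop("rule 'multiply' needs a 'predictor' whose coefficient is scaled")
  structure(list(variable = as.character(variable),
                 stages = if (is.null(stages)) NULL else as.integer(stages),
                 rule = rule, value = as.numeric(value),
                 predictor = predictor, filter = filter),
            class = "intervention_spec")
}

#' Attach an intervention to a simulation configuration
#'
#' Validates the spec against the parameter set and returns a modified
#' configuration whose engine runs realize the override. The unmodified
#' configuration is the natural course.
#'
#' @param ps a `parameter_set`.
#' @param spec an [intervention_spec()].
#' @return the modified `parameter_set`.
#' @export
apply_intervention <- function(ps, spec) {
  stopifnot(inherits(spec, "intervention_spec"))
  if (spec$variable %in% c(SOCIODEM_VARS, NBHD_SOCIO_VARS))
    stop("cannot intervene on time-invariant socio-demographic '",
         spec$variable, "'")
  if (!spec$variable %in% c(ENGINE_VARS, ENV_VARS))
    stop("unknown intervention target '", spec$variable, "'")
  if (spec$variable %in% ENGINE_VARS && !is.null(spec$stages)) {
    app <- applicable_stages(spec$variable, ps$schedule)
    bad <- setdiff(spec$stages, app)
    if (length(bad))
      stop("intervention on '", spec$variable, "' at inapplicable stage(s) ",
           paste(bad, collapse = ", "))
  }
  ps$interventions <- c(ps$interventions, list(spec))
  ps
}

# interventions active for a variable at a stage (stage = NA -> environment)
active_interventions <- function(ps, variable, stage) {
  Filter(function(s) {
    s$variable == variable &&
      (is.na(stage) || is.null(s$stages) || stage %in% s$stages)
  }, ps$interventions)
}

intervention_mask <- function(spec, data) {
  if (is.null(spec$filter)) return(rep(TRUE, nrow(data)))
  mask <- eval(parse(text = spec$filter), envir = data, enclos = baseenv())
  if (!is.logical(mask) || length(mask) != nrow(data))
    stop("intervention filter must evaluate to one logical per row")
  mask & !is.na(mask)
}

#' Contrast an intervention run against the natural course
#'
#' Differences (intervention minus natural) in cumulative incidence and
#' incidence rates for each risk window, and in per-stage prevalence of
#' obesity and diabetes. Both runs must come from the same configuration and
#' cohort size; with paired seeds the contrast reflects the intervention
#' alone (common random numbers), and a null intervention gives exactly
#' zero.
#'
#' @param natural,intervention `obesim_sim` objects (or panels) from
#'   paired runs.
#' @param windows list of [risk_window()]s (default [default_windows()]).
#' @return `data.table` with columns `measure`, `label`, `natural`,
#'   `intervention`, `difference`.
#' @export
contrast <- function(natural, intervention, windows = default_windows()) {
  pn <- if (inherits(natural, "obesim_sim")) natural$panel else as.data.table(natural)
  pi_ <- if (inherits(intervention, "obesim_sim")) intervention$panel else as.data.table(intervention)
  if (nrow(pn) != nrow(pi_) || uniqueN(pn$agent_id) != uniqueN(pi_$agent_id))
    stop("mismatched cohort sizes between natural and intervention panels")
  sched <- attr(pn, "schedule")
  one <- function(panel) {
    mt <- measure_table(panel, windows, strata = "all", schedule = sched)
    ci <- mt[, .(measure = "cumulative_incidence", label = window,
                 value = cum_inc)]
    ir <- mt[, .(measure = "incidence_rate", label = window, value = rate)]
    prev <- rbindlist(lapply(c("obesity", "t2dm"), function(oc) {
      data.table(measure = paste0("prevalence_", oc),
                 label = paste0("stage_", 0:9),
                 value = vapply(0:9, function(t) prevalence(panel, t, oc), 0))
    }))
    rbind(ci, ir, prev)
  }
  a <- one(pn); b <- one(pi_)
  out <- merge(a, b, by = c("measure", "label"), sort = FALSE,
               suffixes = c("_nat", "_int"))
  out[, .(measure, label, natural = value_nat, intervention = value_int,
          difference = value_int - value_nat)]
}

#' Replicate-seed scenario contrast
#'
#' Runs paired natural-course and intervention simulations over several
#' seeds (common random numbers within each pair) and summarizes the
#' Monte-Carlo distribution of each contrast.
#'
#' @param ps the natural-course `parameter_set`.
#' @param spec an [intervention_spec()].
#' @param seeds integer vector of paired replicate seeds.
#' @param windows list of [risk_window()]s.
#' @return list with `by_seed` (per-seed contrasts) and `summary`
#'   (mean, sd and Monte-Carlo range of each difference).
#' @export
scenario_contrast <- function(ps, spec, seeds = 1:20,
                              windows = default_windows()) {
  ps_int <- apply_intervention(ps, spec)
  per <- rbindlist(lapply(seeds, function(s) {
    d <- contrast(run_simulation(ps, seed = s),
                  run_simulation(ps_int, seed = s), windows)
    d[, seed := s]
    d
  }))
  summ <- per[, .(mean_difference = mean(difference),
                  sd_difference = sd(difference),
                  min_difference = min(difference),
                  max_difference = max(difference)),
              by = .(measure, label)]
  list(by_seed = per, summary = summ)
}
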