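# Cohort epidemiologic measures: first events within risk windows,
# person-time, incidence rates and cumulative incidence with Wald confidence
# intervals, age-specific incidence proportions and prevalence.

#' Define a risk window
#'
#' A risk window names an outcome (`"obesity"` or `"t2dm"`), an age span,
#' and implies the at-risk rule: agents already positive at window entry are
#' excluded. Diabetes windows must start at age 18 or later (the condition
#' cannot occur earlier).
#'
#' @param outcome `"obesity"` or `"t2dm"`.
#' @param age_low,age_high window bounds in years, `age_low < age_high`.
#' @return an object of class `risk_window`.
#' @export
risk_window <- function(outcome = c("obesity", "t2dm"), age_low, age_high) {
  outcome <- match.arg(outcome)
  stopifnot(age_low < age_high)
  if (outcome == "t2dm" && age_low < 18)
    stop("t2dm risk windows must start at age >= 18")
  structure(list(outcome = outcome, age_low = age_low, age_high = age_high,
                 label = paste0(outcome, " (", age_low, "-", age_high, ")")),
            class = "risk_window")
}

#' Default risk windows
#'
#' Whole-span obesity (ages 2--65), childhood obesity (2--17), adult obesity
#' (18--65) and adult type 2 diabetes (18--65).
#'
#' @return list of [risk_window()]s.
#' @export
default_windows <- function() {
  list(risk_window("obesity", 2, 65),
       risk_window("obesity", 2, 17),
       risk_window("obesity", 18, 65),
       risk_window("t2dm", 18, 65))
}

outcome_status <- function(panel, outcome) {
  switch(outcome,
         obesity = panel$weight_status == "obese",
         t2dm = panel$t2dm == 1L,
         stop("unknown outcome '", outcome, "'"))
}

window_stages <- function(window, schedule) {
  schedule[age_low >= window$age_low & age_high <= window$age_high, stage]
}

#' First events within a risk window
#'
#' An agent is at risk if not already positive at window entry (its status
#' at the last stage before the window; re-entry is allowed for adult
#' obesity windows, so a child who was obese but reverted before 18 is at
#' risk again). The event stage is the first in-window stage with positive
#' status; the event age is that stage's band midpoint. Agents without an
#' event are censored at the window's upper age bound.
#'
#' @param panel a long-format agent panel.
#' @param window a [risk_window()].
#' @param schedule life-stage schedule (default: the panel's attribute).
#' @return `data.table` with one row per agent: `agent_id`, `at_risk`,
#'   `event`, `age` (event age or censor age).
#' @export
first_events <- function(panel, window, schedule = attr(panel, "schedule")) {
  panel <- as.data.table(panel)
  stages_in <- window_stages(window, schedule)
  if (!length(stages_in)) stop("risk window contains no complete life stage")
  entry <- min(stages_in)
  sub <- panel[stage %in% c(entry - 1L, stages_in)]
  sub <- sub[, .(agent_id, stage, pos = outcome_status(sub, window$outcome))]
  agents <- unique(sub$agent_id)
  prevalent <- if (entry > 0L) sub[stage == entry - 1L & pos, agent_id] else integer()
  hits <- sub[pos & stage >= entry]
  setorder(hits, agent_id, stage)
  firsts <- hits[!duplicated(agent_id), .(agent_id, first_stage = stage)]
  mid <- setNames((schedule$age_low + schedule$age_high) / 2, schedule$stage)
  out <- data.table(agent_id = agents, at_risk = !agents %in% prevalent)
  out <- merge(out, firsts, by = "agent_id", all.x = TRUE, sort = TRUE)
  out[, event := at_risk & !is.na(first_stage)]
  out[, age := ifelse(event, mid[as.character(first_stage)], window$age_high)]
  out[, first_stage := NULL]
  out[]
}

#' Person-years at risk within a window
#'
#' At-risk agents with an event contribute the time from window entry to
#' their event stage's midpoint age; censored agents contribute the full
#' window width.
#'
#' @param fe output of [first_events()].
#' @param window the matching [risk_window()].
#' @return total person-years (numeric scalar).
#' @export
person_time <- function(fe, window) {
  fe <- as.data.table(fe)[at_risk == TRUE]
  sum(ifelse(fe$event, fe$age - window$age_low,
             window$age_high - window$age_low))
}

#' Cumulative incidence with a binomial Wald confidence interval
#'
#' `p = events / n`, interval `p +/- z * sqrt(p (1 - p) / n)`, reported in
#' percent (conventionally printed to 1 decimal).
#'
#' @param events,n first-event and at-risk counts, `0 <= events <= n`,
#'   `n > 0`.
#' @param conf confidence level (default 0.95).
#' @return named numeric: `estimate`, `lower`, `upper`, in percent.
#' @examples
#' round(cumulative_incidence(87625, 98230)["estimate"], 1)  # 89.2
#' @export
cumulative_incidence <- function(events, n, conf = 0.95) {
  if (n <= 0) stop("n must be positive")
  stopifnot(events >= 0, events <= n)
  p <- events / n
  half <- qnorm(1 - (1 - conf) / 2) * sqrt(p * (1 - p) / n)
  c(estimate = 100 * p,
    lower = 100 * max(0, p - half),
    upper = 100 * min(1, p + half))
}

#' Incidence rate per 1,000 person-years with a Poisson Wald interval
#'
#' `r = 1000 * events / person_years`, interval
#' `r +/- z * 1000 * sqrt(events) / person_years`.
#'
#' @param events first-event count.
#' @param person_years person-years at risk (positive).
#' @param conf confidence level (default 0.95).
#' @return named numeric: `estimate`, `lower`, `upper`, per 1,000
#'   person-years.
#' @examples
#' round(incidence_rate(87625, 3183963)["estimate"], 1)  # 27.5
#' @export
incidence_rate <- function(events, person_years, conf = 0.95) {
  if (person_years <= 0) stop("person_years must be positive")
  z <- qnorm(1 - (1 - conf) / 2)
  r <- 1000 * events / person_years
  half <- z * 1000 * sqrt(events) / person_years
  c(estimate = r, lower = max(0, r - half), upper = r + half)
}

#' Age-specific incidence proportion
#'
#' First events at one life stage divided by the at-risk count entering the
#' stage (agents never positive at any earlier stage). Undefined (NA, with a
#' warning) when no agent is at risk.
#'
#' @param panel a long-format agent panel.
#' @param stage stage index.
#' @param outcome `"obesity"` or `"t2dm"`.
#' @param schedule life-stage schedule (default: the panel's attribute).
#' @return proportion (numeric scalar, possibly `NA`).
#' @export
age_specific_incidence <- function(panel, stage, outcome,
                                   schedule = attr(panel, "schedule")) {
  panel <- as.data.table(panel)
  pos <- outcome_status(panel, outcome)
  hits <- panel[pos, .(agent_id, stage)]
  setorder(hits, agent_id, stage)
  firsts <- hits[!duplicated(agent_id), .(agent_id, first_stage = stage)]
  n_total <- uniqueN(panel$agent_id)
  at_risk <- n_total - nrow(firsts[first_stage < stage])
  if (at_risk == 0L) {
    warning("no agents at risk entering stage ", stage, "; incidence undefined")
    return(NA_real_)
  }
  nrow(firsts[first_stage == stage]) / at_risk
}

#' Prevalence at a life stage
#'
#' @param panel a long-format agent panel.
#' @param stage stage index.
#' @param condition `"obesity"` or `"t2dm"`.
#' @return proportion of the cohort positive at that stage.
#' @export
prevalence <- function(panel, stage, condition) {
  panel <- as.data.table(panel)
  keep <- panel[["stage"]] == stage  # resolve against the argument, not the column
  rows <- panel[keep]
  if (nrow(rows) == 0L) stop("no rows at stage ", stage)
  mean(outcome_status(rows, condition))
}

#' Assemble the measure table
#'
#' For every risk window and stratum (overall and by race): at-risk total,
#' first events, person-years, incidence rate per 1,000 person-years with a
#' Poisson Wald interval, and cumulative incidence (percent) with a binomial
#' Wald interval. Verifies that race-stratum totals sum to the overall
#' total; empty strata are omitted with a warning.
#'
#' @param panel a long-format agent panel.
#' @param windows list of [risk_window()]s.
#' @param strata subset of `c("all", "White", "non-White")`.
#' @param schedule life-stage schedule (default: the panel's attribute).
#' @return `data.table`, one row per window x stratum, with columns
#'   `window`, `outcome`, `stratum`, `total_n`, `events`, `person_years`,
#'   `rate`, `rate_lower`, `rate_upper`, `cum_inc`, `cum_lower`,
#'   `cum_upper`.
#' @export
measure_table <- function(panel, windows = default_windows(),
                          strata = c("all", "White", "non-White"),
                          schedule = attr(panel, "schedule")) {
  panel <- as.data.table(panel)
  strata <- match.arg(strata, several.ok = TRUE)
  rows <- list()
  for (w in windows) {
    for (s in strata) {
      sub <- if (s == "all") panel else panel[race == s]
      if (nrow(sub) == 0L) {
        warning("stratum '", s, "' is empty; omitted")
        next
      }
      fe <- first_events(sub, w, schedule)
      n_at_risk <- sum(fe$at_risk)
      ev <- sum(fe$event)
      py <- person_time(fe, w)
      ci <- cumulative_incidence(ev, n_at_risk)
      ir <- incidence_rate(ev, py)
      rows[[length(rows) + 1L]] <- data.table(
        window = w$label, outcome = w$outcome, stratum = s,
        total_n = n_at_risk, events = ev, person_years = py,
        rate = ir[["estimate"]], rate_lower = ir[["lower"]],
        rate_upper = ir[["upper"]],
        cum_inc = ci[["estimate"]], cum_lower = ci[["lower"]],
        cum_upper = ci[["upper"]])
    }
  }
  out <- rbindlist(rows)
  if (all(c("all", "White", "non-White") %in% strata)) {
    chk <- out[, .(ok = .SD[stratum == "all", total_n] ==
                     sum(.SD[stratum != "all", total_n])), by = window]
    if (!all(chk$ok))
      warning("race-stratum totals do not sum to the overall total")
  }
  out[]
}
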