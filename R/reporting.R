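# Descriptive outputs: per-stage trend series (overall and by race) for
# behaviors and outcomes, and the calibration comparison report.

#' Per-stage trend series
#'
#' Per-stage proportions (or means, for BMI) of a behavior or outcome,
#' overall and optionally by race stratum. `"obesity"` reports the
#' weight-status-based prevalence; breastfeeding is defined at stage 0
#' only.
#'
#' @param panel a long-format agent panel.
#' @param variable an engine variable, `"obesity"`, or `"t2dm"`.
#' @param strata `"all"`, `"race"`, or both.
#' @param schedule life-stage schedule (default: the panel's attribute).
#' @return `data.table` with columns `variable`, `stratum`, `stage`,
#'   `age_band`, `value`.
#' @export
trend_series <- function(panel, variable, strata = c("all", "race"),
                         schedule = attr(panel, "schedule")) {
  panel <- as.data.table(panel)
  strata <- match.arg(strata, several.ok = TRUE)
  valid <- c(ENGINE_VARS, "obesity")
  if (!variable %in% valid)
    stop("unknown variable '", variable, "'; expected one of: ",
         paste(valid, collapse = ", "))
  val <- if (variable == "obesity") as.numeric(panel$weight_status == "obese")
         else as.numeric(panel[[variable]])
  dt <- data.table(stage = panel$stage, race = panel$race, value = val)
  # breastfeeding is a first-year exposure; adult-only variables are
  # reported as 0 at child stages (their value by construction)
  stages_keep <- if (variable == "breastfed") 0L else schedule$stage
  dt <- dt[stage %in% stages_keep]
  out <- list()
  if ("all" %in% strata)
    out[[1]] <- dt[, .(stratum = "all", value = mean(value)), by = stage]
  if ("race" %in% strata)
    out[[length(out) + 1L]] <- dt[, .(value = mean(value)),
                                  by = .(stage, stratum = as.character(race))]
  res <- rbindlist(out, use.names = TRUE)
  band <- schedule[, .(stage, age_band = paste0(age_low, "-", age_high))]
  res <- merge(res, band, by = "stage")
  set(res, j = "variable", value = variable)
  setcolorder(res, c("variable", "stratum", "stage", "age_band", "value"))
  setorder(res, stratum, stage)
  res[]
}

#' Calibration comparison report
#'
#' Side-by-side simulated and observed means per variable per stage, with
#' absolute gaps, and the per-variable variance explained (R^2) across
#' stages; R^2 is flagged undefined for variables observed at fewer than
#' three stages.
#'
#' @param sim_means simulated stage means: `data.table` with `variable`,
#'   `stage`, `value` (e.g. from [simulated_stage_means()], or built from
#'   [trend_series()] output).
#' @param targets a calibration target table.
#' @return an object of class `calibration_report`: list with `table`
#'   (per-row comparison) and `r_squared` (per variable, with an
#'   `undefined` flag).
#' @export
calibration_report <- function(sim_means, targets) {
  sim_means <- as.data.table(sim_means)
  targets <- as.data.table(targets)
  tab <- merge(targets[, .(variable, stage, observed = observed_value)],
               sim_means[, .(variable, stage, simulated = value)],
               by = c("variable", "stage"), all.x = TRUE)
  if (anyNA(tab$simulated))
    stop("simulated means missing for some targeted (variable, stage) rows")
  tab[, gap := abs(simulated - observed)]
  setorder(tab, variable, stage)
  r2 <- tab[, .(n_points = .N, r2 = r_squared(simulated, observed)),
            by = variable]
  r2[, undefined := n_points < 3L]
  structure(list(table = tab[], r_squared = r2[]),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("<calibration_report>", nrow(x$table), "compared cells; max gap",
      signif(max(x$table$gap), 3), "\n")
  print(x$r_squared)
  invisible(x)
}

#' Plot trend series
#'
#' Line plot of one or more trend series by stage (requires ggplot2).
#' Tables remain the canonical artifact; this is a convenience for
#' interactive use.
#'
#' @param ts output of [trend_series()] (rows from several variables may be
#'   bound together).
#' @return a ggplot object.
#' @export
plot_trends <- function(ts) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ts <- as.data.table(ts)
  ggplot2::ggplot(ts, ggplot2::aes(x = stage, y = value,
                                   colour = stratum,
                                   linetype = variable)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = 0:9) +
    ggplot2::labs(x = "life stage", y = "proportion / mean") +
    ggplot2::theme_minimal()
}
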