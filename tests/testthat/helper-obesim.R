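library(data.table)

# small default-configuration cohort for fast tests
tiny_ps <- function(seed = 1L, nb = 6L, agents = 40L) {
  default_parameter_set(seed, n_neighborhoods = nb,
                        agents_per_neighborhood = agents)
}

# Benchmark cohort table (n = 98,230): published first-event counts,
# person-years and at-risk totals per risk window and race stratum, with the
# printed incidence rates (per 1,000 py), cumulative incidences (%) and
# their 95% CIs. Inputs for the arithmetic and CI reproduction tests.
benchmark_table1 <- function() {
  w <- c("ob_all", "ob_child", "ob_adult", "t2dm")
  rbindlist(list(
    data.table(stratum = "all", window = w, n = 98230,
               events = c(87625, 31544, 79606, 52426),
               py = c(3183963, 1415891, 2847196, 4099783),
               rate = c(27.5, 22.3, 28.0, 12.8),
               rate_lo = c(27.3, 22.0, 27.8, 12.7),
               rate_hi = c(27.7, 22.5, 28.2, 12.9),
               cum = c(89.2, 32.1, 81.0, 53.4),
               cum_lo = c(89.0, 31.8, 80.8, 53.1),
               cum_hi = c(89.4, 32.4, 81.3, 53.7)),
    data.table(stratum = "White", window = w, n = 35862,
               events = c(31072, 10023, 28067, 14162),
               py = c(1245482, 523022, 1090448, 1571629),
               rate = c(25.0, 19.2, 25.7, 9.0),
               rate_lo = c(24.7, 18.8, 25.4, 8.9),
               rate_hi = c(25.2, 19.5, 26.0, 9.2),
               cum = c(86.6, 28.0, 78.3, 39.5),
               cum_lo = c(86.3, 27.5, 77.8, 38.9),
               cum_hi = c(87.0, 28.4, 78.7, 40.0)),
    data.table(stratum = "non-White", window = w, n = 62368,
               events = c(56553, 21521, 51539, 38264),
               py = c(1938481, 892869, 1756748, 2528154),
               rate = c(29.2, 24.1, 29.3, 15.1),
               rate_lo = c(28.9, 23.8, 29.1, 15.0),
               rate_hi = c(29.4, 24.4, 29.6, 15.3),
               cum = c(90.7, 34.5, 82.6, 61.4),
               cum_lo = c(90.4, 34.1, 82.3, 61.0),
               # the published upper bound for non-White adult obesity
               # (89.3) is inconsistent with its own counts (Wald gives
               # 82.9); flagged NA here and skipped in CI checks
               cum_hi = c(90.9, 34.9, NA, 61.7))
  ))
}

# minimal panel for measure-function unit tests: obesity/diabetes status
# matrices are agents x stages (0-9)
toy_panel <- function(obese, t2dm = NULL, race = NULL) {
  sched <- life_stage_schedule()
  n <- nrow(obese)
  if (is.null(t2dm)) t2dm <- matrix(0L, n, 10)
  if (is.null(race)) race <- rep("White", n)
  panel <- rbindlist(lapply(0:9, function(t) {
    data.table(agent_id = seq_len(n), stage = t,
               age = (sched$age_low[t + 1] + sched$age_high[t + 1]) / 2,
               race = factor(race, levels = c("White", "non-White")),
               weight_status = factor(
                 ifelse(obese[, t + 1] == 1, "obese", "normal"),
                 levels = c("underweight", "normal", "overweight", "obese")),
               t2dm = as.integer(t2dm[, t + 1]))
  }))
  setattr(panel, "schedule", sched)
  panel
}
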