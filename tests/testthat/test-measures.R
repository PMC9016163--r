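# Incidence, prevalence and person-time measures.

test_that("first events and at-risk rules follow the window definition", {
  # agent 1: obese from stage 1 on -> event at the first in-window stage
  # agent 2: never obese -> censored
  # agent 3: obese at stage 0 (before the 2-65 window) -> not at risk
  ob <- rbind(c(0, 1, 1, 1, 1, 1, 1, 1, 1, 1),
              rep(0, 10),
              c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1))
  panel <- toy_panel(ob)
  w <- risk_window("obesity", 2, 65)
  fe <- first_events(panel, w)
  expect_equal(fe$at_risk, c(TRUE, TRUE, FALSE))
  expect_equal(fe$event, c(TRUE, FALSE, FALSE))
  expect_equal(fe$age[1], 3.5)   # stage-1 band midpoint (2-5)
  expect_equal(fe$age[2], 65)    # censored at window end

  # adult window re-entry: obese in childhood but reverted by stage 3
  ob2 <- rbind(c(0, 0, 1, 0, 0, 1, 0, 0, 0, 0),  # reverted: at risk again
               c(0, 0, 0, 1, 0, 1, 0, 0, 0, 0))  # obese at 13-17: prevalent
  fe2 <- first_events(toy_panel(ob2), risk_window("obesity", 18, 65))
  expect_equal(fe2$at_risk, c(TRUE, FALSE))
  expect_equal(fe2$event, c(TRUE, FALSE))
  expect_equal(fe2$age[1], 27)   # stage-5 midpoint (25-29)
})

test_that("person-time accrues window width for censored, midpoint for events", {
  w <- risk_window("obesity", 2, 17)
  none <- toy_panel(matrix(0L, 5, 10))
  fe <- first_events(none, w)
  expect_equal(person_time(fe, w), 5 * 15)
  all_first <- toy_panel(cbind(0, matrix(1L, 4, 9)))
  fe2 <- first_events(all_first, w)
  expect_lt(person_time(fe2, w), 4 * 15)
  expect_equal(person_time(fe2, w), 4 * (3.5 - 2))
  # additivity: doubling the cohort doubles person-years
  dbl <- rbindlist(list(none, copy(none)[, agent_id := agent_id + 100L]))
  setattr(dbl, "schedule", life_stage_schedule())
  expect_equal(person_time(first_events(dbl, w), w),
               2 * person_time(fe, w))
})

test_that("cumulative incidence and rates match their formulas", {
  ci <- cumulative_incidence(87625, 98230)
  expect_equal(round(ci[["estimate"]], 1), 89.2)
  ci0 <- cumulative_incidence(0, 500)
  expect_equal(unname(ci0), c(0, 0, 0))
  expect_error(cumulative_incidence(1, 0), "positive")

  ir <- incidence_rate(21521, 892869)
  expect_equal(round(ir[["estimate"]], 1), 24.1)
  expect_equal(unname(incidence_rate(0, 1000)[["estimate"]]), 0)
  expect_error(incidence_rate(5, 0), "positive")

  # monotone under added events at fixed denominators
  expect_gt(cumulative_incidence(60, 100)[["estimate"]],
            cumulative_incidence(50, 100)[["estimate"]])
  expect_gt(incidence_rate(60, 1000)[["estimate"]],
            incidence_rate(50, 1000)[["estimate"]])
})

test_that("age-specific incidence counts first events among those entering at risk", {
  # 4 agents: first obese at stages 2, 2, 3, never
  ob <- rbind(c(0, 0, 1, 1, 0, 0, 0, 0, 0, 0),
              c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0),
              c(0, 0, 0, 1, 0, 0, 0, 0, 0, 0),
              rep(0, 10))
  panel <- toy_panel(ob)
  expect_equal(age_specific_incidence(panel, 2, "obesity"), 2 / 4)
  expect_equal(age_specific_incidence(panel, 3, "obesity"), 1 / 2)
  all_conv <- toy_panel(cbind(matrix(0L, 3, 4), matrix(1L, 3, 6)))
  expect_equal(age_specific_incidence(all_conv, 4, "obesity"), 1)
  none_left <- toy_panel(matrix(1L, 3, 10))
  expect_warning(res <- age_specific_incidence(none_left, 5, "obesity"),
                 "undefined")
  expect_true(is.na(res))
})

test_that("prevalence is the positive fraction at a stage", {
  all_ob <- toy_panel(matrix(1L, 4, 10))
  expect_equal(prevalence(all_ob, 3, "obesity"), 1)
  none <- toy_panel(matrix(0L, 4, 10))
  expect_equal(prevalence(none, 3, "obesity"), 0)
})

test_that("the measure table is internally consistent across strata", {
  sim <- run_simulation(tiny_ps(nb = 10L, agents = 60L), seed = 6)
  mt <- measure_table(sim$panel)
  expect_equal(nrow(mt), 4 * 3)
  for (w in unique(mt$window)) {
    sub <- mt[window == w]
    expect_equal(sub[stratum == "all", total_n],
                 sum(sub[stratum != "all", total_n]))
    expect_equal(sub[stratum == "all", events],
                 sum(sub[stratum != "all", events]))
  }
  # each cell's cumulative incidence is events / total
  expect_equal(mt$cum_inc, 100 * mt$events / mt$total_n)
  # person-years bounded by cohort x window width
  widths <- c("obesity (2-65)" = 63, "obesity (2-17)" = 15,
              "obesity (18-65)" = 47, "t2dm (18-65)" = 47)
  expect_true(all(mt$person_years <= mt$total_n * widths[mt$window] + 1e-9))
})

test_that("empty strata are omitted with a warning", {
  panel <- toy_panel(matrix(0L, 4, 10), race = rep("non-White", 4))
  expect_warning(mt <- measure_table(panel, windows = default_windows()[2]),
                 "empty")
  expect_false("White" %in% mt$stratum)
})
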