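# Equation evaluation and cohort advancement.

test_that("expit is the inverse logit", {
  expect_equal(expit(0), 0.5)
  expect_equal(expit(log(0.25 / 0.75)), 0.25)
  x <- seq(-10, 10, by = 0.5)
  expect_true(all(diff(expit(x)) > 0))
  expect_true(all(expit(x) > 0 & expit(x) < 1))
})

test_that("equation evaluation matches its definition", {
  # identity, no noise: pure arithmetic
  eq <- equation_spec("bmi", 4, "identity", intercept = 22,
                      terms = data.frame(predictor = "ssb", lag = 0,
                                         coefficient = 1))
  expect_equal(evaluate_equation(eq, data.frame(ssb = 3)), 25)
  # saturated logit: outcome 0 with probability ~ 1
  eq2 <- equation_spec("t2dm", 5, "logit", intercept = -50)
  expect_true(all(evaluate_equation(eq2, data.frame(x = numeric(1000))) == 0L))
  # zero coefficients, logit: Bernoulli(1/2)
  eq3 <- equation_spec("ssb", 1, "logit", intercept = 0)
  set.seed(1)
  draws <- evaluate_equation(eq3, data.frame(x = numeric(20000)))
  expect_lt(abs(mean(draws) - 0.5), 0.02)
  # missing predictor is a named error
  eq4 <- equation_spec("bmi", 4, "identity", 0,
                       terms = data.frame(predictor = "activity", lag = 1,
                                          coefficient = 1))
  expect_error(evaluate_equation(eq4, data.frame(activity = 1)),
               "predictor 'activity' \\(lag 1\\)")
})

test_that("smoking, alcohol, diabetes and marriage are zero before age 18", {
  sim <- run_simulation(tiny_ps(), seed = 2)
  child <- sim$panel[stage <= 3]
  expect_true(all(child$smoking == 0L))
  expect_true(all(child$alcohol == 0L))
  expect_true(all(child$t2dm == 0L))
  expect_true(all(child$marital == 0L))
  expect_true(all(child$age < 18))
})

test_that("diagnosed diabetes is absorbing within agents", {
  sim <- run_simulation(tiny_ps(nb = 10L, agents = 60L), seed = 3)
  mono <- sim$panel[order(agent_id, stage),
                    .(ok = all(diff(t2dm) >= 0)), by = agent_id]
  expect_true(all(mono$ok))
  # and with a strongly positive hazard, prior cases stay cases
  ps <- tiny_ps()
  for (t in 5:9) ps$equations[[paste0("t2dm@", t)]]$intercept <- -50
  ps$equations[["t2dm@4"]]$intercept <- 10  # nearly everyone converts at 18-24
  sim2 <- run_simulation(ps, seed = 3)
  wide <- dcast(sim2$panel[stage >= 4], agent_id ~ stage, value.var = "t2dm")
  expect_true(all(wide[["9"]] >= wide[["4"]]))
  expect_gt(mean(wide[["4"]]), 0.95)
})

test_that("identity lag dynamics preserve BMI when the lag coefficient is 1", {
  ps <- tiny_ps()
  ps$equations[["bmi@1"]] <- equation_spec(
    "bmi", 1, "identity", intercept = 0,
    terms = data.frame(predictor = "bmi", lag = 1, coefficient = 1),
    noise_sd = 0)
  set.seed(4)
  nb <- build_neighborhoods(ps)
  a0 <- build_agents(nb, ps)
  a1 <- step(a0, nb, ps, 1L)
  expect_equal(a1$bmi, a0$bmi)
})

test_that("full runs are bit-identical under the same seed", {
  ps <- tiny_ps(nb = 8L, agents = 50L)
  s1 <- run_simulation(ps, seed = 11)
  s2 <- run_simulation(ps, seed = 11)
  for (cl in names(s1$panel)) expect_identical(s1$panel[[cl]], s2$panel[[cl]])
  expect_identical(as.data.frame(s1$neighborhoods),
                   as.data.frame(s2$neighborhoods))
  s3 <- run_simulation(ps, seed = 12)
  expect_false(identical(s1$panel$bmi, s3$panel$bmi))
})

test_that("positive sugar-sweetened-beverage effects raise adult BMI", {
  ps_pos <- tiny_ps(nb = 10L, agents = 80L)
  ps_zero <- ps_pos
  for (t in 0:9) {
    k <- paste0("bmi@", t)
    tm <- copy(ps_zero$equations[[k]]$terms)
    tm[predictor == "ssb", coefficient := 0]
    ps_zero$equations[[k]]$terms <- tm
  }
  diffs <- vapply(1:3, function(s) {
    m_pos <- run_simulation(ps_pos, seed = s)$panel[stage >= 4, mean(bmi)]
    m_zero <- run_simulation(ps_zero, seed = s)$panel[stage >= 4, mean(bmi)]
    m_pos - m_zero
  }, 0)
  expect_true(all(diffs > 0))
})

test_that("the BMI feedback on activity is live and sign-correct", {
  ps <- tiny_ps(nb = 10L, agents = 80L)
  set.seed(21)
  nb <- build_neighborhoods(ps)
  a0 <- build_agents(nb, ps)
  for (t in 1:3) { set.seed(100 + t); a0 <- step(a0, nb, ps, t) }
  hi <- copy(a0)[, bmi := bmi + 5]
  set.seed(55); nxt_lo <- step(a0, nb, ps, 4L)
  set.seed(55); nxt_hi <- step(hi, nb, ps, 4L)
  # with a negative lag-BMI coefficient and coupled uniforms, raising BMI
  # can only switch activity off, never on
  expect_true(all(nxt_hi$activity <= nxt_lo$activity))
  expect_lt(mean(nxt_hi$activity), mean(nxt_lo$activity))
})

test_that("the cohort is closed: same agents present at every stage", {
  sim <- run_simulation(tiny_ps(), seed = 5)
  counts <- sim$panel[, .N, by = stage]
  expect_equal(unique(counts$N), tiny_ps()$population_size)
  ids0 <- sort(sim$panel[stage == 0, agent_id])
  for (t in 1:9) expect_equal(sort(sim$panel[stage == t, agent_id]), ids0)
})
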