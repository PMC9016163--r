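# Neighborhood and cohort synthesis.

test_that("neighborhood and agent counts follow the configuration exactly", {
  ps <- tiny_ps(nb = 7L, agents = 23L)
  set.seed(1)
  nb <- build_neighborhoods(ps)
  expect_equal(nrow(nb), 7L)
  agents <- build_agents(nb, ps)
  expect_equal(nrow(agents), 7L * 23L)
  expect_equal(unname(table(agents$neighborhood_id)), rep(23L, 7L),
               ignore_attr = TRUE)
})

test_that("degenerate (sd = 0) distributions give identical neighborhoods", {
  ps <- tiny_ps()
  ps$nbhd_dist[, sd := 0]
  set.seed(2)
  nb <- build_neighborhoods(ps)
  for (v in c("pct_nonwhite", "pct_below_fpl", "pct_bachelor"))
    expect_equal(var(nb[[v]]), 0)
})

test_that("population synthesis is deterministic under a fixed seed", {
  ps <- tiny_ps()
  set.seed(9); nb1 <- build_neighborhoods(ps); a1 <- build_agents(nb1, ps)
  set.seed(9); nb2 <- build_neighborhoods(ps); a2 <- build_agents(nb2, ps)
  expect_equal(as.data.frame(nb1), as.data.frame(nb2))
  expect_equal(as.data.frame(a1), as.data.frame(a2))
})

test_that("agent race and income concentrate on neighborhood composition", {
  ps <- tiny_ps(nb = 2L, agents = 200L)
  set.seed(3)
  nb <- build_neighborhoods(ps)
  nb[1, pct_nonwhite := 0]
  nb[2, pct_nonwhite := 1]
  agents <- build_agents(nb, ps)
  expect_true(all(agents[neighborhood_id == 1, race] == "White"))
  expect_true(all(agents[neighborhood_id == 2, race] == "non-White"))

  # Bernoulli mean property: regressing agent race on neighborhood
  # composition over many neighborhoods recovers slope ~ 1
  ps2 <- tiny_ps(nb = 150L, agents = 40L)
  set.seed(4)
  nb2 <- build_neighborhoods(ps2)
  ag2 <- build_agents(nb2, ps2)
  d <- merge(ag2[, .(race_num = mean(race == "non-White")), by = neighborhood_id],
             nb2[, .(neighborhood_id = id, pct_nonwhite)], by = "neighborhood_id")
  slope <- coef(lm(race_num ~ pct_nonwhite, d))[2]
  expect_lt(abs(slope - 1), 0.1)
})

test_that("ages are uniform within the stage band", {
  sched <- life_stage_schedule()
  set.seed(5)
  a0 <- draw_age(0L, sched, 5000L)
  expect_true(all(a0 >= 0 & a0 <= 1))
  a9 <- draw_age(9L, sched, 10000L)
  expect_true(all(a9 >= 60 & a9 <= 65))
  expect_lt(abs(mean(a9) - 62.5), 0.1)
  expect_error(draw_age(10L, sched), "out of range")
})

test_that("environment prediction follows its equations", {
  ps <- tiny_ps()
  # zero coefficients and noise: attributes equal intercepts
  for (v in c("walkability", "park_access", "supermarket_density",
              "fastfood_density")) {
    k <- paste0(v, "@env")
    ps$equations[[k]]$terms$coefficient <- rep(0, nrow(ps$equations[[k]]$terms))
    ps$equations[[k]]$noise_sd <- 0
  }
  socio <- data.table(pct_nonwhite = 0.5, pct_below_fpl = 0.2,
                      pct_bachelor = 0.3)
  env <- predict_environment(socio, ps)
  expect_equal(env$walkability, ps$equations[["walkability@env"]]$intercept)
  expect_equal(env$fastfood_density,
               max(0, ps$equations[["fastfood_density@env"]]$intercept))
  # with zero noise, identical inputs give identical outputs
  expect_equal(predict_environment(socio, ps), env)

  # default coefficients: expected fast-food density rises with poverty
  ps2 <- tiny_ps()
  set.seed(6)
  poor <- predict_environment(
    data.table(pct_nonwhite = 0.5, pct_below_fpl = rep(0.6, 1000),
               pct_bachelor = 0.3), ps2)
  rich <- predict_environment(
    data.table(pct_nonwhite = 0.5, pct_below_fpl = rep(0.05, 1000),
               pct_bachelor = 0.3), ps2)
  expect_gt(mean(poor$fastfood_density), mean(rich$fastfood_density))
})

test_that("socio-demographics are time-invariant within agents", {
  sim <- run_simulation(tiny_ps(), seed = 8)
  inv <- sim$panel[, .(race = uniqueN(race), sex = uniqueN(sex),
                       ses = uniqueN(ses_group),
                       nbhd = uniqueN(neighborhood_id)), by = agent_id]
  expect_true(all(inv[, .(race, sex, ses, nbhd)] == 1L))
})
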