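# Parameter configuration: defaults, validation, and text round-trip.

test_that("default configuration has the declared population structure", {
  ps <- default_parameter_set(1)
  expect_equal(ps$n_neighborhoods, 235L)
  expect_equal(ps$agents_per_neighborhood, 418L)
  expect_equal(ps$population_size, 98230L)
  expect_equal(nrow(ps$schedule), 10L)
  expect_equal(ps$schedule$age_low[1], 0)
  expect_equal(ps$schedule$age_high[10], 65)
  expect_length(validate_parameter_set(ps), 0)
})

test_that("default synthesis is deterministic in the seed", {
  expect_equal(default_parameter_set(7), default_parameter_set(7))
})

test_that("adult-only variables have no child-stage equations and birth has no lags", {
  ps <- tiny_ps()
  keys <- names(ps$equations)
  for (v in c("smoking", "alcohol", "t2dm", "marital")) {
    for (t in 0:3) expect_false(paste0(v, "@", t) %in% keys)
    for (t in 4:9) expect_true(paste0(v, "@", t) %in% keys)
  }
  stage0 <- Filter(function(e) !is.na(e$stage) && e$stage == 0L, ps$equations)
  expect_gt(length(stage0), 0)
  for (eq in stage0) expect_true(all(eq$terms$lag == 0L))
})

test_that("validation names broken invariants", {
  ps <- tiny_ps()
  bad <- ps
  bad$equations[["bmi@3"]]$noise_sd <- -1
  v <- validate_parameter_set(bad)
  expect_length(v, 1)
  expect_match(v, "noise_sd")

  bad <- ps
  bad$equations[["ssb@3"]] <- NULL
  v <- validate_parameter_set(bad)
  expect_length(v, 1)
  expect_match(v, "missing equation for 'ssb' at stage 3")

  bad <- ps
  bad$equations[["t2dm@2"]] <- equation_spec("t2dm", 2, "logit", -3)
  v <- validate_parameter_set(bad)
  expect_true(any(grepl("adult-only", v)))

  bad <- ps
  bad$targets <- rbind(ps$targets,
                       data.table(variable = "ssb", stage = 99L,
                                  observed_value = 1.2, scale = "proportion"))
  v <- validate_parameter_set(bad)
  expect_length(v, 1)
  expect_match(v, "outside \\[0,1\\]")

  lagged0 <- equation_spec("ssb", 0, "logit", 0,
                           terms = data.frame(predictor = "ssb", lag = 1,
                                              coefficient = 1))
  bad <- ps
  bad$equations[["ssb@0"]] <- lagged0
  expect_true(any(grepl("stage 0", validate_parameter_set(bad))))
})

test_that("target-table validation flags duplicates and bad scales", {
  tt <- default_target_table()
  expect_length(validate_target_table(tt), 0)
  dup <- rbind(tt, tt[1])
  expect_match(validate_target_table(dup), "duplicate")
})

test_that("save/load round-trips the configuration and its simulations", {
  ps <- tiny_ps(seed = 11)
  dir <- withr::local_tempdir()
  save_parameter_set(ps, dir)
  ps2 <- load_parameter_set(dir)
  expect_equal(ps2$equations, ps$equations, ignore_attr = TRUE)
  expect_equal(as.data.frame(ps2$schedule), as.data.frame(ps$schedule))
  expect_equal(as.data.frame(ps2$nbhd_dist), as.data.frame(ps$nbhd_dist))
  expect_equal(as.data.frame(ps2$targets), as.data.frame(ps$targets))
  expect_equal(ps2$population_size, ps$population_size)
  expect_equal(ps2$bmi_clip, ps$bmi_clip)
  s1 <- run_simulation(ps, seed = 3)
  s2 <- run_simulation(ps2, seed = 3)
  for (cl in names(s1$panel)) expect_identical(s1$panel[[cl]], s2$panel[[cl]])
})

test_that("loading an inconsistent configuration fails atomically, naming the gap", {
  ps <- tiny_ps()
  dir <- withr::local_tempdir()
  save_parameter_set(ps, dir)
  # graft a diabetes equation onto a child stage
  meta <- fread(file.path(dir, "equations.tsv"))
  coefs <- fread(file.path(dir, "coefficients.tsv"))
  meta <- rbind(meta, data.table(variable = "t2dm", stage = 2L, link = "logit",
                                 noise_sd = 0, evidence_level = "synthetic"))
  coefs <- rbind(coefs, data.table(variable = "t2dm", stage = 2L,
                                   predictor = "(Intercept)", lag = 0L,
                                   coefficient = -3,
                                   evidence_level = "synthetic"))
  fwrite(meta, file.path(dir, "equations.tsv"), sep = "\t")
  fwrite(coefs, file.path(dir, "coefficients.tsv"), sep = "\t")
  expect_error(load_parameter_set(dir), "adult-only")

  # remove an equation entirely
  dir2 <- withr::local_tempdir()
  save_parameter_set(ps, dir2)
  meta <- fread(file.path(dir2, "equations.tsv"))
  fwrite(meta[!(variable == "ffv" & stage == 5)],
         file.path(dir2, "equations.tsv"), sep = "\t")
  expect_error(load_parameter_set(dir2), "missing equation for 'ffv' at stage 5")
})

test_that("equation accessor errors on absent equations", {
  ps <- tiny_ps()
  expect_error(get_equation(ps, "t2dm", 1), "no equation")
  expect_s3_class(get_equation(ps, "t2dm", 5), "equation_spec")
})
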