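# Calibration-in-the-large: sequential per-stage grid search over intercepts
# and feedback coefficients minimizing the mean absolute error between
# simulated and observed stage means/proportions, with common random numbers
# across grid points, plus R^2 internal validation.

#' Mean absolute error between simulated and observed means
#'
#' Either two matched numeric vectors, or two tables with columns
#' `variable`, `stage` and a value column (`value` for the simulated side,
#' `observed_value` for targets), joined on (variable, stage).
#'
#' @param sim simulated means (numeric vector or table).
#' @param obs observed means (numeric vector or target table).
#' @return mean over variables of `|sim - obs|`.
#' @examples
#' mae(c(0.4, 0.5), c(0.3, 0.5))  # 0.05
#' @export
mae <- function(sim, obs) {
  if (is.numeric(sim) && is.numeric(obs)) {
    if (length(sim) != length(obs)) stop("sim and obs lengths differ")
    return(mean(abs(sim - obs)))
  }
  sim <- as.data.table(sim); obs <- as.data.table(obs)
  valcol <- if ("observed_value" %in% names(obs)) "observed_value" else "value"
  j <- merge(sim[, .(variable, stage, sim_value = value)],
             obs[, .(variable, stage, obs_value = get(valcol))],
             by = c("variable", "stage"))
  if (nrow(j) != nrow(obs))
    stop("variable mismatch: ", nrow(obs) - nrow(j),
         " observed rows have no simulated counterpart")
  mean(abs(j$sim_value - j$obs_value))
}

#' Variance explained between simulated and observed series
#'
#' `1 - SS_residual / SS_total` of the paired points, where `SS_total` is
#' taken about the observed mean. Undefined (returns `NA`) with fewer than
#' three paired points.
#'
#' @param sim,obs paired numeric vectors (e.g. stage means).
#' @return numeric, or `NA_real_` when fewer than 3 points.
#' @examples
#' r_squared(c(1, 2, 4), c(1, 2, 3))  # 0.5
#' @export
r_squared <- function(sim, obs) {
  stopifnot(length(sim) == length(obs))
  keep <- !is.na(sim) & !is.na(obs)
  sim <- sim[keep]; obs <- obs[keep]
  if (length(obs) < 3L) return(NA_real_)
  1 - sum((obs - sim)^2) / sum((obs - mean(obs))^2)
}

#' Grid specification for one tunable coefficient
#'
#' @param variable,stage the equation whose parameter is tuned.
#' @param parameter `"(Intercept)"` or the name of a predictor whose
#'   coefficient is tuned (e.g. the lag-1 `"bmi"` feedback term of the
#'   activity equation).
#' @param lower,upper grid bounds, `lower < upper`.
#' @param points number of grid points (at least 3).
#' @param refine refinement rounds: after the coarse pass the grid is
#'   re-centered on the best point with 5x finer spacing.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(variable, stage, parameter = "(Intercept)",
                      lower, upper, points = 41L, refine = 1L) {
  stopifnot(lower < upper, points >= 3L, refine >= 0L)
  structure(list(variable = as.character(variable), stage = as.integer(stage),
                 parameter = as.character(parameter),
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 points = as.integer(points), refine = as.integer(refine)),
            class = "grid_spec")
}

#' Default calibration grids
#'
#' Intercept grids for every targeted (variable, stage): centered on the
#' equation's current intercept, with half-width 2 on the logit scale for
#' logistic equations and `2 * max(noise_sd, 1)` for identity-link
#' equations; 41 points, one 5x refinement round. For the activity equation
#' the lag-1 BMI feedback coefficient is tuned jointly with the intercept on
#' `[0, 2] x` its initial value (21 points).
#'
#' @param ps a `parameter_set`.
#' @param targets a calibration target table.
#' @param tune_feedback tune the activity feedback coefficient jointly
#'   (default `TRUE`).
#' @return list of [grid_spec()]s.
#' @export
default_grids <- function(ps, targets, tune_feedback = TRUE) {
  targets <- as.data.table(targets)
  grids <- list()
  for (i in seq_len(nrow(targets))) {
    v <- targets$variable[i]; t <- targets$stage[i]
    eq <- get_equation(ps, v, t)
    # centered on the configuration's current intercept: with lagged and
    # covariate terms the intercept is offset from link(p_obs) by the
    # expected term contribution, so link(p_obs) is a poor grid center
    if (eq$link == "logit") {
      grids[[length(grids) + 1L]] <- grid_spec(v, t, "(Intercept)",
                                               eq$intercept - 2,
                                               eq$intercept + 2, 41L)
    } else {
      hw <- 2 * max(eq$noise_sd, 1)
      grids[[length(grids) + 1L]] <- grid_spec(v, t, "(Intercept)",
                                               eq$intercept - hw,
                                               eq$intercept + hw, 41L)
    }
    if (tune_feedback && v == "activity" && t > 0) {
      fb <- eq$terms[predictor == "bmi" & lag == 1L, coefficient]
      if (length(fb) == 1L && fb != 0) {
        rng <- sort(c(0, 2 * fb))
        grids[[length(grids) + 1L]] <- grid_spec(v, t, "bmi",
                                                 rng[1], rng[2], 21L)
      }
    }
  }
  grids
}

grids_for <- function(grids, variable, stage) {
  Filter(function(g) g$variable == variable && g$stage == stage, grids)
}

# deterministic sub-seed for (replicate, stage, variable-slot); keeps every
# derived seed well inside 32-bit integer range
cal_subseed <- function(seed, r, t, k) {
  (((seed %% 65011L) * 2011L + r * 7919L + (t + 1L) * 613L + k * 101L)
   %% 2147483629L) + 1L
}

# agent base state (socio-demographics + neighborhood attributes), used by
# the calibration forward pass; draw order mirrors build_agents()
init_agent_base <- function(neighborhoods, ps) {
  m <- ps$agents_per_neighborhood
  n <- nrow(neighborhoods) * m
  cur <- data.table(agent_id = seq_len(n),
                    neighborhood_id = rep(neighborhoods$id, each = m))
  cur <- merge(cur, neighborhoods, by.x = "neighborhood_id", by.y = "id",
               sort = FALSE)
  setorder(cur, agent_id)
  cur[, race := as.integer(runif(n) < pct_nonwhite)]
  cur[, ses_group := as.integer(runif(n) < pct_below_fpl)]
  cur[, sex := as.integer(runif(n) < ps$sex_prob)]
  cur
}

# forward pass of the calibration engine: walks stages 0..max_stage with
# `replicates` parallel cohorts sharing derived random streams; when grids
# and targets are supplied, tunes each gridded equation before realizing it
# (common random numbers across grid points). Without grids it simply
# reports simulated stage means under `ps`.
cal_forward <- function(ps, replicates, seed, targets = NULL, grids = NULL,
                        max_stage = 9L) {
  R <- replicates
  tuned <- ps
  targets <- if (!is.null(targets)) as.data.table(targets)
  states <- vector("list", R)
  for (r in seq_len(R)) {
    set.seed(cal_subseed(seed, r, -1L, 0L))
    nb <- build_neighborhoods(ps)
    states[[r]] <- init_agent_base(nb, ps)
  }
  n <- nrow(states[[1]])
  means <- list(); gaps <- list(); trace <- list()

  for (t in 0:max_stage) {
    for (r in seq_len(R)) {
      set.seed(cal_subseed(seed, r, t, 0L))
      states[[r]][, age := draw_age(t, ps$schedule, n)]
    }
    pre_gaps <- c(); post_gaps <- c()
    for (k in seq_along(ENGINE_VARS)) {
      v <- ENGINE_VARS[k]
      if (!t %in% applicable_stages(v, ps$schedule)) {
        for (r in seq_len(R)) set(states[[r]], j = v,
                                  value = if (v == "bmi") NA_real_ else 0L)
        next
      }
      spec <- get_equation(tuned, v, t)
      # pre-drawn randomness shared by every grid candidate (CRN)
      rand <- lapply(seq_len(R), function(r) {
        set.seed(cal_subseed(seed, r, t, k))
        if (spec$link == "logit") runif(n) else rnorm(n, 0, spec$noise_sd)
      })
      # linear predictor excluding the tunable parameters
      gset <- if (is.null(grids)) list() else grids_for(grids, v, t)
      coef_g <- Filter(function(g) g$parameter != "(Intercept)", gset)
      coef_g <- if (length(coef_g)) coef_g[[1]] else NULL
      base_spec <- spec
      base_spec$intercept <- 0  # intercept always added back as cur_alpha
      xfb <- NULL
      if (!is.null(coef_g)) {
        i <- which(base_spec$terms$predictor == coef_g$parameter)
        if (!length(i)) stop("grid parameter '", coef_g$parameter,
                             "' not in equation ", v, "@", t)
        i <- i[1]
        lagged <- base_spec$terms$lag[i] == 1L
        xfb <- lapply(states, function(st)
          st[[if (lagged) paste0("lag_", coef_g$parameter) else coef_g$parameter]])
        base_spec$terms <- copy(base_spec$terms)[i, coefficient := 0]
      }
      bases <- lapply(states, function(st) linear_predictor(base_spec, st))

      realize_mean <- function(alpha, beta) {
        vals <- vapply(seq_len(R), function(r) {
          lp <- bases[[r]] + alpha +
            (if (is.null(xfb)) 0 else beta * xfb[[r]])
          if (spec$link == "logit") {
            x <- as.integer(rand[[r]] < expit(lp))
            if (v == "t2dm" && !is.null(states[[r]][["lag_t2dm"]]))
              x <- pmax(x, states[[r]][["lag_t2dm"]])
            mean(x)
          } else {
            x <- lp + rand[[r]]
            if (v == "bmi") x <- pmin(ps$bmi_clip[2], pmax(ps$bmi_clip[1], x))
            mean(x)
          }
        }, 0)
        mean(vals)
      }

      tgt <- if (!is.null(targets))
        targets[variable == v & stage == t, observed_value] else numeric()
      cur_alpha <- spec$intercept
      cur_beta <- if (is.null(coef_g)) 0 else {
        i <- which(spec$terms$predictor == coef_g$parameter)
        spec$terms$coefficient[i[1]]
      }

      if (length(gset) && length(tgt) == 1L) {
        pre_gaps <- c(pre_gaps, abs(realize_mean(cur_alpha, cur_beta) - tgt))
        int_g <- Filter(function(g) g$parameter == "(Intercept)", gset)
        int_g <- if (length(int_g)) int_g[[1]] else NULL
        avals <- if (is.null(int_g)) cur_alpha
                 else seq(int_g$lower, int_g$upper, length.out = int_g$points)
        bvals <- if (is.null(coef_g)) cur_beta
                 else seq(coef_g$lower, coef_g$upper, length.out = coef_g$points)
        pick <- function(avals, bvals) {
          cand <- as.matrix(expand.grid(alpha = avals, beta = bvals))
          score <- vapply(seq_len(nrow(cand)), function(j)
            abs(realize_mean(cand[j, 1], cand[j, 2]) - tgt), 0)
          # ties broken toward the smallest coefficient magnitudes
          ord <- order(score, abs(cand[, 1]) + abs(cand[, 2]))
          cand[ord[1], ]
        }
        best <- pick(avals, bvals)
        rounds <- max(vapply(gset, function(g) g$refine, 0L))
        for (rr in seq_len(rounds)) {
          sa <- if (length(avals) > 1) diff(avals[1:2]) else 0
          sb <- if (length(bvals) > 1) diff(bvals[1:2]) else 0
          avals <- if (sa > 0) seq(best[1] - sa, best[1] + sa,
                                   length.out = 11L) else best[1]
          bvals <- if (sb > 0) seq(best[2] - sb, best[2] + sb,
                                   length.out = 11L) else best[2]
          best <- pick(avals, bvals)
        }
        cur_alpha <- best[[1]]; cur_beta <- best[[2]]
        key <- eq_key(v, t)
        tuned$equations[[key]]$intercept <- cur_alpha
        if (!is.null(coef_g)) {
          i <- which(tuned$equations[[key]]$terms$predictor == coef_g$parameter)
          tuned$equations[[key]]$terms <-
            copy(tuned$equations[[key]]$terms)[i[1], coefficient := cur_beta]
        }
      }

      # realize the variable under the (possibly tuned) parameters
      real_means <- numeric(R)
      for (r in seq_len(R)) {
        lp <- bases[[r]] + cur_alpha +
          (if (is.null(xfb)) 0 else cur_beta * xfb[[r]])
        val <- if (spec$link == "logit") {
          x <- as.integer(rand[[r]] < expit(lp))
          if (v == "t2dm" && !is.null(states[[r]][["lag_t2dm"]]))
            x <- pmax(x, states[[r]][["lag_t2dm"]])
          x
        } else {
          x <- lp + rand[[r]]
          if (v == "bmi") x <- pmin(ps$bmi_clip[2], pmax(ps$bmi_clip[1], x))
          x
        }
        set(states[[r]], j = v, value = val)
        real_means[r] <- mean(val)
      }
      mu <- mean(real_means)
      means[[length(means) + 1L]] <- data.table(variable = v, stage = t,
                                                value = mu)
      if (length(tgt) == 1L) {
        post_gaps <- c(post_gaps, abs(mu - tgt))
        gaps[[length(gaps) + 1L]] <- data.table(variable = v, stage = t,
                                                observed = tgt, simulated = mu,
                                                gap = abs(mu - tgt))
      }
    }
    trace[[length(trace) + 1L]] <- data.table(
      stage = t,
      mae_pre = if (length(pre_gaps)) mean(pre_gaps) else NA_real_,
      mae_post = if (length(post_gaps)) mean(post_gaps) else NA_real_)
    # roll current values into lag columns for the next stage
    for (r in seq_len(R)) {
      st <- states[[r]]
      for (v in ENGINE_VARS) set(st, j = paste0("lag_", v), value = st[[v]])
    }
  }
  list(ps = tuned, means = rbindlist(means), gaps = rbindlist(gaps),
       mae_trace = rbindlist(trace))
}

#' Simulated stage means under a configuration
#'
#' Average, over replicate cohorts with derived random streams, of each
#' engine variable's mean at each stage. This is the quantity calibration
#' scores against the target table; running it on a known configuration is
#' the standard way to generate synthetic calibration targets.
#'
#' @param ps a `parameter_set`.
#' @param replicates number of replicate cohorts.
#' @param seed integer seed.
#' @return `data.table` with columns `variable`, `stage`, `value`.
#' @export
simulated_stage_means <- function(ps, replicates = 3L, seed = 1L) {
  cal_forward(ps, replicates, seed)$means
}

#' Calibrate one life stage
#'
#' Simulates the cohort through `stage` with all earlier stages frozen at
#' their current parameters, and grid-searches the stage's tunable
#' parameters (intercepts, and optionally feedback coefficients) to minimize
#' the absolute gap to each target. Every grid point is scored on the mean
#' of `replicates` cohorts sharing common random numbers.
#'
#' @param ps a `parameter_set` whose stages `< stage` are already tuned.
#' @param targets calibration target table.
#' @param stage the stage to tune.
#' @param grids list of [grid_spec()]s (default: [default_grids()] filtered
#'   to `stage`).
#' @param replicates replicate cohorts per grid point.
#' @param seed integer seed.
#' @return list with `ps` (tuned), `gaps`, `mae_trace`.
#' @export
calibrate_stage <- function(ps, targets, stage, grids = NULL,
                            replicates = 3L, seed = 1L) {
  targets <- as.data.table(targets)
  if (is.null(grids))
    grids <- default_grids(ps, targets[targets$stage == stage])
  grids <- Filter(function(g) g$stage == stage, grids)
  res <- cal_forward(ps, replicates, seed, targets = targets, grids = grids,
                     max_stage = stage)
  list(ps = res$ps, gaps = res$gaps[res$gaps$stage == stage],
       mae_trace = res$mae_trace)
}

#' Calibration-in-the-large over all life stages
#'
#' Sequentially, from birth to the last stage, tunes each targeted
#' equation's intercept (and, where gridded, feedback coefficient) so the
#' simulated stage mean matches the observed mean or proportion, scoring
#' every grid point on `replicates` cohorts with common random numbers and
#' refining the grid once around the optimum. Earlier stages are frozen as
#' later ones are tuned. Internal validation reports the per-variable R^2
#' between simulated and observed series across stages (undefined for
#' variables observed at fewer than three stages).
#'
#' @param ps a `parameter_set`.
#' @param targets calibration target table covering every calibrated
#'   (variable, stage).
#' @param grids list of [grid_spec()]s (default [default_grids()]).
#' @param replicates replicate cohorts per grid point (default 3).
#' @param seed integer seed; calibration is deterministic given it.
#' @return an object of class `calibration_result`: list with `ps` (tuned
#'   parameter set), `mae_trace` (per-stage MAE before/after tuning),
#'   `gaps` (per-variable final absolute gaps), `r_squared`, `replicates`,
#'   `seed`.
#' @export
calibrate <- function(ps, targets, grids = NULL, replicates = 3L, seed = 1L) {
  targets <- as.data.table(targets)
  viol <- validate_target_table(targets)
  if (length(viol)) stop(paste(viol, collapse = "; "))
  if (is.null(grids)) grids <- default_grids(ps, targets)
  for (g in grids) {
    if (nrow(targets[variable == g$variable & stage == g$stage]) == 0L)
      stop("missing target for calibrated variable '", g$variable,
           "' at stage ", g$stage)
  }
  res <- cal_forward(ps, replicates, seed, targets = targets, grids = grids,
                     max_stage = 9L)
  r2 <- merge(res$means, targets[, .(variable, stage, observed_value)],
              by = c("variable", "stage"))
  r2 <- r2[, .(n_points = .N, r2 = r_squared(value, observed_value)),
           by = variable]
  structure(list(ps = res$ps, mae_trace = res$mae_trace, gaps = res$gaps,
                 r_squared = r2, replicates = replicates, seed = seed),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> replicates:", x$replicates, "seed:", x$seed, "\n")
  cat("final MAE by stage:\n")
  print(x$mae_trace)
  invisible(x)
}
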