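# Child BMI z-scores via the LMS transformation and weight-status
# classification with WHO-style child z-score cutoffs and standard adult BMI
# cutoffs.

#' Synthetic LMS growth reference
#'
#' A smooth, synthetic BMI-for-age LMS reference table covering 0--240
#' months for both sexes, built from spline anchors that mimic the familiar
#' shape of pediatric BMI references (high infant median, adiposity rebound
#' around ages 5--6, rise through adolescence). It is NOT a published
#' growth standard: it exists so the simulator and its tests are
#' self-contained. Users with access to the CDC or WHO tables can supply
#' them in the same column layout (`sex`, `age_months`, `L`, `M`, `S`).
#'
#' @param by_months grid spacing of the table in months.
#' @return `data.table` with columns `sex` (`"male"`/`"female"`),
#'   `age_months`, `L`, `M`, `S`.
#' @export
default_growth_reference <- function(by_months = 3) {
  months <- seq(0, 240, by = by_months)
  yrs <- months / 12
  M <- spline(x = c(0, 0.5, 1, 2, 4, 6, 9, 12, 15, 17, 20),
              y = c(13.4, 16.2, 16.8, 16.0, 15.6, 15.9, 16.8, 18.2, 19.5, 20.3, 21.0),
              xout = yrs, method = "natural")$y
  L <- spline(x = c(0, 5, 10, 15, 20),
              y = c(-0.8, -1.6, -1.8, -1.6, -1.4),
              xout = yrs, method = "natural")$y
  S <- spline(x = c(0, 5, 9, 13, 17, 20),
              y = c(0.085, 0.082, 0.080, 0.090, 0.100, 0.105),
              xout = yrs, method = "natural")$y
  male <- data.table(sex = "male", age_months = months, L = L, M = M, S = S)
  # slightly lower median and higher relative spread for girls
  female <- data.table(sex = "female", age_months = months, L = L,
                       M = M * 0.985, S = S * 1.03)
  rbind(male, female)
}

#' LMS z-score
#'
#' Skew-normalizing z-score of a measurement against LMS reference
#' parameters: `z = ((x/M)^L - 1) / (L * S)` when `L != 0`, and
#' `z = log(x/M) / S` in the `L -> 0` limit. Vectorized.
#'
#' @param bmi positive measurement (here BMI, kg/m^2).
#' @param L,M,S reference parameters (`M`, `S` positive).
#' @return numeric z-score(s).
#' @examples
#' lms_zscore(20, L = -2, M = 16, S = 0.1)  # 1.8
#' @export
lms_zscore <- function(bmi, L, M, S) {
  stopifnot(all(bmi > 0), all(M > 0), all(S > 0))
  out <- ifelse(abs(L) < 1e-7,
                log(bmi / M) / S,
                ((bmi / M)^L - 1) / (L * S))
  as.numeric(out)
}

# interpolate L, M, S at given ages (years) for one or more agents
lms_lookup <- function(sex, age_years, reference) {
  reference <- as.data.table(reference)
  months <- age_years * 12
  out <- data.table(L = rep(NA_real_, length(months)), M = NA_real_, S = NA_real_)
  for (s in unique(sex)) {
    ref <- reference[sex == s][order(age_months)]
    if (nrow(ref) == 0L) stop("growth reference has no rows for sex '", s, "'")
    idx <- which(sex == s)
    m <- months[idx]
    if (any(m < min(ref$age_months) - 1e-9 | m > max(ref$age_months) + 1e-9))
      stop("age outside growth-reference coverage (",
           min(ref$age_months), "-", max(ref$age_months), " months)")
    set(out, idx, "L", approx(ref$age_months, ref$L, xout = m, rule = 1)$y)
    set(out, idx, "M", approx(ref$age_months, ref$M, xout = m, rule = 1)$y)
    set(out, idx, "S", approx(ref$age_months, ref$S, xout = m, rule = 1)$y)
  }
  out
}

#' BMI z-score against a growth reference
#'
#' Looks up `L`, `M`, `S` by sex and age (linear interpolation between the
#' bracketing reference ages) and applies [lms_zscore()].
#'
#' @param bmi BMI in kg/m^2.
#' @param sex `"male"`/`"female"` (recycled if length 1).
#' @param age_years age in years; must lie within reference coverage.
#' @param reference an LMS table (default [default_growth_reference()]).
#' @return numeric z-score(s).
#' @export
bmi_zscore <- function(bmi, sex, age_years,
                       reference = default_growth_reference()) {
  n <- max(length(bmi), length(sex), length(age_years))
  bmi <- rep_len(bmi, n); sex <- rep_len(sex, n); age_years <- rep_len(age_years, n)
  lms <- lms_lookup(sex, age_years, reference)
  lms_zscore(bmi, lms$L, lms$M, lms$S)
}

#' Child weight status from a BMI z-score
#'
#' Cutoffs: underweight `z < -2`; normal `-2 <= z < 1`; overweight
#' `1 <= z < 2`; obese `z >= 2`. Boundaries are left-closed.
#'
#' @param z BMI z-score(s).
#' @return factor with levels underweight/normal/overweight/obese.
#' @export
classify_child <- function(z) {
  idx <- findInterval(z, c(-2, 1, 2)) + 1L
  factor(WEIGHT_LEVELS[idx], levels = WEIGHT_LEVELS)
}

#' Adult weight status from BMI
#'
#' Cutoffs: underweight `< 18.5`; normal `18.5--25`; overweight `25--30`;
#' obese `>= 30` kg/m^2. Boundaries are left-closed.
#'
#' @param bmi BMI in kg/m^2 (positive).
#' @return factor with levels underweight/normal/overweight/obese.
#' @export
classify_adult <- function(bmi) {
  stopifnot(all(bmi > 0))
  idx <- findInterval(bmi, c(18.5, 25, 30)) + 1L
  factor(WEIGHT_LEVELS[idx], levels = WEIGHT_LEVELS)
}

#' Weight status, dispatching on age
#'
#' Agents under 18 are classified by the child z-score cutoffs, agents 18
#' and over by the adult BMI cutoffs (the z-score argument is ignored for
#' adults). The dispatch age of 18 aligns the anthropometric rule with the
#' model's adult-stage boundary.
#'
#' @param age age(s) in years.
#' @param bmi BMI in kg/m^2.
#' @param z child BMI z-score (required where `age < 18`).
#' @return factor with levels underweight/normal/overweight/obese.
#' @examples
#' classify_weight(age = 40, bmi = 27)            # overweight
#' classify_weight(age = 10, bmi = 22, z = 2.5)   # obese
#' @export
classify_weight <- function(age, bmi, z = NA_real_) {
  n <- max(length(age), length(bmi), length(z))
  age <- rep_len(age, n); bmi <- rep_len(bmi, n); z <- rep_len(z, n)
  child <- age < 18
  if (any(child & is.na(z)))
    stop("z-score required to classify agents under 18")
  out <- factor(rep(NA_character_, n), levels = WEIGHT_LEVELS)
  if (any(child)) out[child] <- classify_child(z[child])
  if (any(!child)) out[!child] <- classify_adult(bmi[!child])
  out
}
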