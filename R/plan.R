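#' Default per-day behaviour-time parameters (minutes)
#'
#' Means and SDs of daily minutes per behaviour and day type for a
#' night-shift manufacturing cohort: long LPA and short sleep on
#' workdays, the reverse on leisure days.
#' @return named list of data.frames (`workday`, `leisure`) with rows
#'   `sb`, `lpa`, `mvpa`, `sleep` and columns `mean`, `sd`.
#' @export
default_behavior_params <- function() {
  list(
    workday = data.frame(
      row.names = c("sb", "lpa", "mvpa", "sleep"),
      mean = c(372.2, 599.3, 68.9, 294.7),
      sd = c(124.2, 127.6, 37.8, 68.4)),
    leisure = data.frame(
      row.names = c("sb", "lpa", "mvpa", "sleep"),
      mean = c(383.8, 215.0, 28.6, 549.3),
      sd = c(104.2, 79.8, 21.6, 119.3)))
}

#' Default outcome-model parameters
#'
#' Marginal means/SDs of the 11 risk factors (log10 scale for TG and the
#' liver enzymes) and the planted per-30-min substitution structure: a
#' gamma coefficient per (outcome, day type, behaviour) in the partition
#' parameterization, so the true effect of reallocating time from
#' behaviour A to behaviour B is `gamma_B - gamma_A`. Defaults plant
#' exactly three non-zero gammas, chosen so the five direction cells a
#' field analyst would expect light up (workday SB->LPA lowers waist
#' circumference; workday sleep->SB and sleep->MVPA raise TG; leisure
#' SB->MVPA and sleep->MVPA lower AST) while every other contrast on the
#' reporting surface is null. This is a calibration device, not a claim
#' about true physiology.
#'
#' @return list with `marginals` (data.frame outcome/mean/sd/log) and
#'   `gamma` (array outcome x day_type x behaviour).
#' @export
default_outcome_params <- function() {
  marg <- data.frame(
    outcome = OUTCOMES,
    mean = c(69.5, 23.7, 84.8, 121.9, 75.2, 55.7, 115.4,
             2.0, 1.4, 1.5, 1.7),
    sd = c(9.7, 3.5, 9.3, 13.0, 9.6, 14.2, 27.4,
           0.3, 0.1, 0.2, 0.3),
    log = OUTCOMES %in% LOG_OUTCOMES,
    stringsAsFactors = FALSE)
  gamma <- array(0, dim = c(length(OUTCOMES), 2L, length(BEHAVIORS)),
                 dimnames = list(OUTCOMES, DAY_TYPES, BEHAVIORS))
  gamma["wc", "workday", "lpa"] <- -0.8    # cm per 30 min
  gamma["tg", "workday", "sleep"] <- -0.05 # log10 mg/dL per 30 min
  gamma["ast", "leisure", "mvpa"] <- -0.04 # log10 U/L per 30 min
  list(marginals = marg, gamma = gamma)
}

#' Build a synthetic-cohort plan
#'
#' The plan is the complete stated world of the generator: cohort and
#' exclusion-cascade sizes, the alternating night-shift calendar
#' (arrival 18:30, 24 h at the company, about 10.8 shifts/month), wear
#' protocol, per-day behaviour-time distributions, covariate
#' distributions and the outcome model with its planted substitution
#' effects.
#'
#' @param n_participants analysis-cohort size (default 66).
#' @param n_employees total regular employees for the exclusion roster.
#' @param n_day_workers day workers removed before eligibility.
#' @param exclusions named counts for stages `no_consent`, `not_worn`,
#'   `no_exam`, `short_wear`.
#' @param shifts_per_month_mean,shifts_per_month_sd night shifts per
#'   30-day month.
#' @param wear_days_mean,wear_days_sd accelerometer wear days.
#' @param n_workdays_mean,n_workdays_sd,n_leisure_mean,n_leisure_sd
#'   wear-day composition used by the fast participant-level generator.
#' @param calendar_days length of the simulated calendar (days).
#' @param behavior_params see [default_behavior_params()].
#' @param sleep_offset_min minutes from window start (18:30) to the main
#'   sleep block: 570 puts workday sleep in the 04:00-10:00 in-company
#'   free-time block; 330 puts leisure sleep at midnight.
#' @param age_mean,age_sd,drinker_prop covariate distributions.
#' @param age_coef,alcohol_coef true covariate effects on every outcome
#'   (default 0; behaviours carry the planted signal).
#' @param outcome_params see [default_outcome_params()].
#' @param noise_scale multiplier on all outcome noise SDs.
#' @param delta reallocation unit the gammas are expressed in (minutes).
#' @param mets_ranges uniform METs ranges used for wake epochs.
#' @return object of class `cohort_plan`.
#' @export
cohort_plan <- function(n_participants = 66, n_employees = 157,
                        n_day_workers = 24,
                        exclusions = c(no_consent = 2, not_worn = 44,
                                       no_exam = 15, short_wear = 6),
                        shifts_per_month_mean = 10.8,
                        shifts_per_month_sd = 2.0,
                        wear_days_mean = 6.2, wear_days_sd = 1.3,
                        n_workdays_mean = 1.9, n_workdays_sd = 0.6,
                        n_leisure_mean = 4.2, n_leisure_sd = 1.1,
                        calendar_days = 30,
                        behavior_params = default_behavior_params(),
                        sleep_offset_min = c(workday = 570, leisure = 330),
                        age_mean = 40.2, age_sd = 9.9,
                        drinker_prop = 0.59,
                        age_coef = 0, alcohol_coef = 0,
                        outcome_params = default_outcome_params(),
                        noise_scale = 1, delta = 30,
                        mets_ranges = list(sb = c(0.9, 1.5),
                                           lpa = c(1.6, 2.9),
                                           mvpa = c(3.0, 6.0))) {
  stopifnot(n_participants >= 1, n_employees >= 1,
            all(exclusions >= 0), n_day_workers >= 0,
            wear_days_sd >= 0, shifts_per_month_sd >= 0,
            noise_scale >= 0, delta > 0)
  if (n_day_workers + sum(exclusions) > n_employees)
    stop("exclusion counts exceed the employee population")
  for (dt in DAY_TYPES) {
    bp <- behavior_params[[dt]]
    stopifnot(all(bp$sd >= 0))
    if (sum(bp$mean) > DAY_MIN)
      stop(sprintf("behaviour means for %s days exceed 1440 minutes", dt))
  }
  structure(mget(names(formals(cohort_plan)), envir = environment()),
            class = "cohort_plan")
}

#' @export
print.cohort_plan <- function(x, ...) {
  cat(sprintf(
    "cohort_plan: %d participants (%d employees), %.1f shifts/month, %.1f wear days\n",
    x$n_participants, x$n_employees, x$shifts_per_month_mean,
    x$wear_days_mean))
  invisible(x)
}

# One RNG substream per participant and stage, derived from the master
# seed so per-participant output is stable under cohort-size changes.
participant_seed <- function(seed, i, stage) {
  (abs(seed) %% 65011 * 30011 + i * 1009 + stage * 97) %% 2147483629
}
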