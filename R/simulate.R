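clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate per-participant shift calendars and work rosters
#'
#' Builds, for each participant, a calendar of `plan$calendar_days` days
#' anchored at 18:30 company-arrival boundaries. The base pattern
#' alternates workday/leisure day; workdays are then randomly converted
#' to leisure (weekly consecutive leisure day, monthly closure, paid
#' holidays) until the participant's target shift count, drawn from the
#' plan's shifts-per-month distribution, is met. Each workday is one
#' roster interval: arrival at 18:30, departure 24 h later. A contiguous
#' wear window containing at least one day of each type is chosen for
#' the accelerometer protocol.
#'
#' @param plan a [cohort_plan()].
#' @param n number of participants (default `plan$n_participants`).
#' @param seed master seed; every source of randomness derives from it.
#' @param start calendar origin (first possible arrival instant).
#' @return list with `calendar` (data.frame participant_id/day_index/
#'   day_type/worn/start), `roster` (participant_id/arrival/departure)
#'   and `start`.
#' @export
generate_calendar <- function(plan, n = plan$n_participants, seed = 1,
                              start = as.POSIXct("2018-09-03 18:30:00",
                                                 tz = "UTC")) {
  nd <- plan$calendar_days
  day_s <- DAY_MIN * 60
  cal <- vector("list", n)
  ros <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(participant_seed(seed, i, 1L))
    target <- round(rnorm(1, plan$shifts_per_month_mean,
                          plan$shifts_per_month_sd))
    base_work <- seq(1L, nd, by = 2L)
    target <- clamp(target, 0L, length(base_work))
    drop_n <- length(base_work) - target
    work_days <- sort(if (drop_n > 0)
      setdiff(base_work, sample(base_work, drop_n)) else base_work)
    day_type <- rep("leisure", nd)
    day_type[work_days] <- "workday"

    wear <- clamp(round(rnorm(1, plan$wear_days_mean, plan$wear_days_sd)),
                  3L, nd)
    ok_starts <- Filter(function(s) {
      w <- day_type[s:(s + wear - 1L)]
      any(w == "workday") && any(w == "leisure")
    }, seq_len(nd - wear + 1L))
    ws <- if (length(ok_starts)) ok_starts[sample.int(length(ok_starts), 1L)]
          else 1L
    worn <- seq_len(nd) %in% ws:(ws + wear - 1L)

    pid <- sprintf("P%03d", i)
    cal[[i]] <- data.frame(
      participant_id = pid, day_index = seq_len(nd), day_type = day_type,
      worn = worn,
      start = start + (seq_len(nd) - 1L) * day_s,
      stringsAsFactors = FALSE)
    if (length(work_days))
      ros[[i]] <- data.frame(
        participant_id = pid,
        arrival = start + (work_days - 1L) * day_s,
        departure = start + work_days * day_s,
        stringsAsFactors = FALSE)
  }
  list(calendar = do.call(rbind, cal), roster = do.call(rbind, ros),
       start = start)
}

# Sequential truncated-normal day draws: sleep, MVPA, LPA, SB, each
# bounded at 0 and the day's remaining budget (sleep also at the block
# that fits after its scheduled onset); SB absorbs the tightest budget,
# the remainder is non-wear.
draw_day_minutes <- function(plan, day_type, n) {
  bp <- plan$behavior_params[[day_type]]
  sleep_cap <- DAY_MIN - plan$sleep_offset_min[[day_type]]
  out <- matrix(0, n, 4, dimnames = list(NULL, c("sleep", "mvpa",
                                                 "lpa", "sb")))
  remaining <- rep(DAY_MIN, n)
  for (b in colnames(out)) {
    cap <- if (b == "sleep") pmin(remaining, sleep_cap) else remaining
    x <- clamp(rnorm(n, bp[b, "mean"], bp[b, "sd"]), 0, cap)
    out[, b] <- x
    remaining <- remaining - x
  }
  cbind(out[, BEHAVIORS, drop = FALSE], nonwear = remaining)
}

# Round continuous day minutes to the 1-minute epoch grid; a rounding
# overflow (at most 2 min) is taken out of SB, non-wear is the slack.
round_day_minutes <- function(mins) {
  m <- round(mins)
  over <- sum(m[BEHAVIORS]) - DAY_MIN
  if (over > 0) m["sb"] <- m["sb"] - over
  m["nonwear"] <- DAY_MIN - sum(m[BEHAVIORS])
  m
}

# Lay one day's integer minutes onto a 1-minute grid: main sleep as a
# single block at its scheduled onset, then MVPA, LPA, SB and non-wear
# filling the remaining slots in order.
layout_day_epochs <- function(pid, day_start, m, sleep_offset, plan) {
  lab <- rep("nonwear", DAY_MIN)
  sl <- m[["sleep"]]
  sleep_idx <- if (sl > 0) seq(sleep_offset + 1L, sleep_offset + sl) else
    integer(0)
  lab[sleep_idx] <- "sleep"
  rest <- setdiff(seq_len(DAY_MIN), sleep_idx)
  fill <- c(rep("mvpa", m[["mvpa"]]), rep("lpa", m[["lpa"]]),
            rep("sb", m[["sb"]]))
  lab[rest[seq_along(fill)]] <- fill
  state <- c(sb = "wake", lpa = "wake", mvpa = "wake",
             sleep = "main_sleep", nonwear = "nonwear")[lab]
  mets <- rep(NA_real_, DAY_MIN)
  for (b in c("sb", "lpa", "mvpa")) {
    sel <- lab == b
    r <- plan$mets_ranges[[b]]
    mets[sel] <- runif(sum(sel), r[1], r[2])
  }
  data.frame(participant_id = pid,
             start = day_start + (seq_len(DAY_MIN) - 1L) * 60,
             duration_s = 60, state = unname(state), mets = mets,
             stringsAsFactors = FALSE)
}

#' Generate epoch-level accelerometer streams with known ground truth
#'
#' Emits a 1-minute epoch grid for every worn calendar day: a contiguous
#' main-sleep block placed in the in-company free-time window (04:00-
#' 10:00) on workdays and around midnight on leisure days, wake epochs
#' with METs drawn uniformly inside each behaviour's band, and non-wear
#' filling the slack. Per-day minutes are sequential truncated-normal
#' draws at the plan's parameters and are recorded as ground truth, so
#' extraction can be checked by round trip.
#'
#' @param plan a [cohort_plan()].
#' @param calendar output of [generate_calendar()].
#' @param seed master seed.
#' @return list with `epochs` (epoch table) and `ground_truth`
#'   (data.frame participant_id/day_index/day_type + planted minutes per
#'   behaviour and non-wear).
#' @export
generate_epochs <- function(plan, calendar, seed = 1) {
  cal <- calendar$calendar
  ids <- unique(cal$participant_id)
  eps <- list(); gts <- list()
  for (i in seq_along(ids)) {
    set.seed(participant_seed(seed, i, 2L))
    ci <- cal[cal$participant_id == ids[i] & cal$worn, , drop = FALSE]
    if (!nrow(ci)) next
    # draw all worn days in calendar order, one type at a time is wrong:
    # draws must be per-day in day order for reproducibility
    day_rows <- lapply(seq_len(nrow(ci)), function(j) {
      dt <- ci$day_type[j]
      m <- round_day_minutes(draw_day_minutes(plan, dt, 1L)[1L, ])
      ep <- layout_day_epochs(ids[i], ci$start[j], m,
                              plan$sleep_offset_min[[dt]], plan)
      list(ep = ep,
           gt = data.frame(participant_id = ids[i],
                           day_index = ci$day_index[j], day_type = dt,
                           start = ci$start[j],
                           t(m), stringsAsFactors = FALSE))
    })
    eps[[i]] <- do.call(rbind, lapply(day_rows, `[[`, "ep"))
    gts[[i]] <- do.call(rbind, lapply(day_rows, `[[`, "gt"))
  }
  list(epochs = do.call(rbind, eps), ground_truth = do.call(rbind, gts))
}

#' Generate participant covariates (age, alcohol status)
#'
#' @param plan a [cohort_plan()].
#' @param n cohort size.
#' @param seed master seed.
#' @return data.frame `participant_id`, `age` (years), `alcohol` (1 =
#'   drinker).
#' @export
generate_covariates <- function(plan, n = plan$n_participants, seed = 1) {
  age <- numeric(n); alcohol <- integer(n)
  for (i in seq_len(n)) {
    set.seed(participant_seed(seed, i, 3L))
    age[i] <- clamp(rnorm(1, plan$age_mean, plan$age_sd), 20, 65)
    alcohol[i] <- rbinom(1, 1, plan$drinker_prop)
  }
  data.frame(participant_id = sprintf("P%03d", seq_len(n)), age = age,
             alcohol = alcohol, stringsAsFactors = FALSE)
}

#' Generate risk-factor outcomes from planted substitution effects
#'
#' Each outcome is linear in the per-day-type behaviour means expressed
#' in `delta`-minute units, with the plan's partition-model gamma
#' coefficients, optional covariate effects and Gaussian noise.
#' Log-flagged outcomes are generated on the log10 scale and
#' exponentiated, so the emitted value is in natural units (mg/dL, U/L).
#' Intercepts are chosen so marginal outcome means match the plan's
#' marginals at the plan's behaviour means.
#'
#' @param plan a [cohort_plan()].
#' @param timeuse data.frame with `participant_id` and the eight
#'   `<behavior>_<day_type>` mean-minute columns.
#' @param covariates output of [generate_covariates()].
#' @param seed master seed.
#' @return list with `records` (covariates + outcomes in natural units)
#'   and `truth` (the gamma array and per-outcome intercepts/noise SDs).
#' @export
generate_outcomes <- function(plan, timeuse, covariates, seed = 1) {
  op <- plan$outcome_params
  marg <- op$marginals
  gamma <- op$gamma
  n <- nrow(timeuse)
  stopifnot(identical(timeuse$participant_id, covariates$participant_id))

  # linear predictor shared across outcomes: behaviours in delta units
  bmat <- list()
  for (dt in DAY_TYPES)
    bmat[[dt]] <- as.matrix(timeuse[, behavior_cols(dt), drop = FALSE]) /
      plan$delta

  noise <- matrix(NA_real_, n, nrow(marg))
  for (i in seq_len(n)) {
    set.seed(participant_seed(seed, i, 4L))
    noise[i, ] <- rnorm(nrow(marg))
  }

  rec <- covariates
  intercepts <- numeric(nrow(marg)); names(intercepts) <- marg$outcome
  for (k in seq_len(nrow(marg))) {
    oc <- marg$outcome[k]
    mu <- rep(0, n); mu0 <- 0
    for (dt in DAY_TYPES) {
      g <- gamma[oc, dt, ]
      mu <- mu + as.vector(bmat[[dt]] %*% g)
      mu0 <- mu0 + sum(g * plan$behavior_params[[dt]][BEHAVIORS, "mean"] /
                         plan$delta)
    }
    intercepts[k] <- marg$mean[k] - mu0 -
      plan$age_coef * plan$age_mean - plan$alcohol_coef * plan$drinker_prop
    y <- intercepts[k] + mu + plan$age_coef * covariates$age +
      plan$alcohol_coef * covariates$alcohol +
      noise[, k] * marg$sd[k] * plan$noise_scale
    rec[[oc]] <- if (marg$log[k]) 10^y else y
  }
  list(records = rec,
       truth = list(gamma = gamma, intercepts = intercepts,
                    noise_sd = setNames(marg$sd * plan$noise_scale,
                                        marg$outcome)))
}

#' Fast participant-level cohort generator
#'
#' Skips the epoch layer: draws each participant's wear-day composition
#' and per-day behaviour minutes with the same truncated-normal scheme
#' as [generate_epochs()], averages them into day-type means, and
#' generates covariates and outcomes. This is the generator used for
#' simulation studies (parameter recovery, coverage, power) where the
#' epoch round trip is not under test.
#'
#' @param plan a [cohort_plan()].
#' @param n cohort size.
#' @param seed master seed.
#' @return list with `records` (analysis-ready participant table:
#'   covariates, outcomes, behaviour means, day counts) and `truth`
#'   (gamma array etc., see [generate_outcomes()]).
#' @export
generate_cohort <- function(plan, n = plan$n_participants, seed = 1) {
  counts <- matrix(0L, n, 2L)
  means <- matrix(0, n, 8L,
                  dimnames = list(NULL, c(behavior_cols("workday"),
                                          behavior_cols("leisure"))))
  for (i in seq_len(n)) {
    set.seed(participant_seed(seed, i, 2L))
    n_work <- clamp(round(rnorm(1, plan$n_workdays_mean,
                                plan$n_workdays_sd)), 1L, 10L)
    n_leis <- clamp(round(rnorm(1, plan$n_leisure_mean,
                                plan$n_leisure_sd)), 1L, 15L)
    w <- draw_day_minutes(plan, "workday", n_work)
    l <- draw_day_minutes(plan, "leisure", n_leis)
    counts[i, ] <- c(n_work, n_leis)
    means[i, ] <- c(colMeans(w[, BEHAVIORS, drop = FALSE]),
                    colMeans(l[, BEHAVIORS, drop = FALSE]))
  }
  timeuse <- data.frame(participant_id = sprintf("P%03d", seq_len(n)),
                        n_workdays = counts[, 1L],
                        n_leisure_days = counts[, 2L],
                        n_wear_days = counts[, 1L] + counts[, 2L],
                        means, stringsAsFactors = FALSE)
  cov <- generate_covariates(plan, n, seed)
  out <- generate_outcomes(plan, timeuse, cov, seed)
  records <- merge(timeuse, out$records, by = "participant_id",
                   sort = TRUE)
  list(records = records, truth = out$truth)
}

#' Generate the exclusion-cascade cohort-status roster
#'
#' Emits one row per regular employee with stage flags set so that the
#' exclusion cascade reproduces the plan's counts exactly: day workers,
#' non-consenters, device non-wearers, no health exam, short wear, and a
#' clean remainder. Row order is shuffled (deterministically under
#' `seed`); the cascade outcome is order-invariant.
#'
#' @param plan a [cohort_plan()].
#' @param seed master seed.
#' @param included_ids optional ids to use for the clean (included)
#'   rows, e.g. the ids of a generated analysis cohort.
#' @return data.frame `participant_id`, `is_day_worker`, `consented`,
#'   `wore_device`, `has_exam`, `n_wear_days`, `n_workdays`,
#'   `n_leisure_days`.
#' @export
generate_exclusion_roster <- function(plan, seed = 1,
                                      included_ids = NULL) {
  n_inc <- plan$n_employees - plan$n_day_workers - sum(plan$exclusions)
  if (n_inc < 0) stop("exclusion counts exceed the employee population")
  ex <- plan$exclusions
  stage <- c(rep("day_worker", plan$n_day_workers),
             rep("no_consent", ex[["no_consent"]]),
             rep("not_worn", ex[["not_worn"]]),
             rep("no_exam", ex[["no_exam"]]),
             rep("short_wear", ex[["short_wear"]]),
             rep("included", n_inc))
  n <- length(stage)
  ids <- sprintf("E%03d", seq_len(n))
  if (!is.null(included_ids)) {
    if (length(included_ids) != n_inc)
      stop(sprintf("need %d included ids, got %d", n_inc,
                   length(included_ids)))
    ids[stage == "included"] <- included_ids
  }
  df <- data.frame(
    participant_id = ids,
    is_day_worker = stage == "day_worker",
    consented = stage != "no_consent",
    wore_device = !stage %in% c("no_consent", "not_worn"),
    has_exam = stage != "no_exam",
    n_wear_days = ifelse(stage == "included", 6L,
                         ifelse(stage == "short_wear", 2L, 0L)),
    n_workdays = ifelse(stage == "included", 2L,
                        ifelse(stage == "short_wear", 1L, 0L)),
    n_leisure_days = ifelse(stage == "included", 4L,
                            ifelse(stage == "short_wear", 1L, 0L)),
    stringsAsFactors = FALSE)
  set.seed(participant_seed(seed, 0L, 5L))
  df <- df[sample.int(n), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Simulate a full study: calendar, epochs, covariates, outcomes, roster
#'
#' End-to-end convenience wrapper producing everything the extraction
#' and modelling stages consume, plus ground truth for validation.
#'
#' @param plan a [cohort_plan()].
#' @param seed master seed.
#' @param emit_epochs generate the epoch stream (slow for large n); when
#'   `FALSE` only the participant-level fast path is produced.
#' @return list with `epochs`, `roster`, `calendar`, `ground_truth`
#'   (per-day planted minutes), `status` (exclusion roster), `records`
#'   (analysis-ready participant table) and `truth` (outcome model).
#' @export
simulate_study <- function(plan, seed = 1, emit_epochs = TRUE) {
  n <- plan$n_participants
  cal <- generate_calendar(plan, n, seed)
  if (emit_epochs) {
    ge <- generate_epochs(plan, cal, seed)
    gt <- ge$ground_truth
    # day-type means from planted complete days
    rows <- lapply(unique(gt$participant_id), function(pid) {
      g <- gt[gt$participant_id == pid, , drop = FALSE]
      means <- unlist(lapply(DAY_TYPES, function(dt) {
        gg <- g[g$day_type == dt, BEHAVIORS, drop = FALSE]
        setNames(if (nrow(gg)) colMeans(gg) else rep(NA_real_, 4),
                 behavior_cols(dt))
      }))
      data.frame(participant_id = pid,
                 n_workdays = sum(g$day_type == "workday"),
                 n_leisure_days = sum(g$day_type == "leisure"),
                 n_wear_days = nrow(g), as.list(means),
                 stringsAsFactors = FALSE)
    })
    timeuse <- do.call(rbind, rows)
    cov <- generate_covariates(plan, n, seed)
    out <- generate_outcomes(plan, timeuse, cov, seed)
    records <- merge(timeuse, out$records, by = "participant_id",
                     sort = TRUE)
    epochs <- ge$epochs
    truth <- out$truth
  } else {
    co <- generate_cohort(plan, n, seed)
    records <- co$records; truth <- co$truth
    epochs <- NULL; gt <- NULL
  }
  status <- generate_exclusion_roster(plan, seed,
                                      included_ids = records$participant_id)
  list(epochs = epochs, roster = cal$roster, calendar = cal$calendar,
       ground_truth = gt, status = status, records = records,
       truth = truth)
}
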