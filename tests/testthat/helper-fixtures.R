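# Fixture builders shared across test files. Everything is generated in
# code; no data files.

t0 <- function(s = "2018-09-03 18:30:00") as.POSIXct(s, tz = "UTC")

# epoch table from parallel vectors; minutes offset from `origin`
make_epochs <- function(offset_min, duration_min = 1, state = "wake",
                        mets = NA_real_, pid = "A",
                        origin = t0()) {
  n <- length(offset_min)
  data.frame(participant_id = rep_len(pid, n),
             start = origin + offset_min * 60,
             duration_s = rep_len(duration_min, n) * 60,
             state = rep_len(state, n),
             mets = rep_len(mets, n),
             stringsAsFactors = FALSE)
}

# one fully covered synthetic day of 1-min epochs with known minutes
make_full_day <- function(sb = 400, lpa = 500, mvpa = 60, sleep = 300,
                          nonmain = 100, pid = "A", origin = t0()) {
  stopifnot(sb + lpa + mvpa + sleep + nonmain <= 1440)
  nonwear <- 1440 - (sb + lpa + mvpa + sleep + nonmain)
  lab <- rep(c("sleep", "nonmain_sleep", "sb", "lpa", "mvpa", "nonwear"),
             c(sleep, nonmain, sb, lpa, mvpa, nonwear))
  state <- c(sb = "wake", lpa = "wake", mvpa = "wake",
             sleep = "main_sleep", nonmain_sleep = "nonmain_sleep",
             nonwear = "nonwear")[lab]
  mets <- c(sb = 1.2, lpa = 2.0, mvpa = 4.0, sleep = NA, nonmain_sleep = NA,
            nonwear = NA)[lab]
  make_epochs(seq_len(1440) - 1, state = unname(state),
              mets = unname(mets), pid = pid, origin = origin)
}

# random full-rank participant table with all behaviour/outcome columns
random_records <- function(n = 100, seed = 1) {
  set.seed(seed)
  rec <- data.frame(participant_id = sprintf("r%03d", seq_len(n)),
                    age = rnorm(n, 40, 10),
                    alcohol = rbinom(n, 1, 0.6),
                    stringsAsFactors = FALSE)
  means <- list(workday = c(sb = 372, lpa = 599, mvpa = 69, sleep = 295),
                leisure = c(sb = 384, lpa = 215, mvpa = 29, sleep = 549))
  sds <- list(workday = c(124, 128, 38, 68), leisure = c(104, 80, 22, 119))
  for (dt in c("workday", "leisure"))
    for (k in seq_along(BEHAVIORS)) {
      b <- BEHAVIORS[k]
      rec[[paste0(b, "_", dt)]] <-
        pmax(rnorm(n, means[[dt]][[b]], sds[[dt]][k]), 1)
    }
  for (oc in OUTCOMES)
    rec[[oc]] <- exp(rnorm(n, 1, 0.3)) + 1  # positive, usable when logged
  rec
}

# small plan without the exclusion scaffolding, for epoch-level tests
tiny_plan <- function(n = 4, ...) {
  cohort_plan(n_participants = n, n_employees = n, n_day_workers = 0,
              exclusions = c(no_consent = 0, not_worn = 0, no_exam = 0,
                             short_wear = 0), ...)
}
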