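#' Aggregate classified epochs into per-day time use
#'
#' Sums epoch durations by behaviour within each day window. An epoch
#' belongs to the window containing its start time (windows are
#' half-open). Epochs falling outside every window are dropped with a
#' warning. Empty windows yield an all-zero row. A day is `complete` when
#' it is not a partial edge window and its epochs cover the full 24 h to
#' within `coverage_tol_min`.
#'
#' @param epochs epoch table; classified with [classify_epochs()] first if
#'   no `behavior` column is present (validation included either way).
#' @param windows day windows from [label_days()].
#' @param coverage_tol_min tolerance (minutes) when deciding full coverage.
#' @return data.frame with one row per window: identifiers, `day_type`,
#'   minute totals `sb`, `lpa`, `mvpa`, `sleep`, `nonmain_sleep`,
#'   `nonwear`, plus `covered_min`, `partial`, `complete`.
#' @export
aggregate_timeuse <- function(epochs, windows, coverage_tol_min = 1) {
  if (!"behavior" %in% names(epochs)) {
    epochs <- classify_epochs(epochs)
  } else {
    epochs <- validate_epochs(epochs)
  }
  classes <- c(BEHAVIORS, "nonmain_sleep", "nonwear")
  rows <- vector("list", nrow(windows))
  unassigned <- 0L
  for (pid in unique(windows$participant_id)) {
    w <- windows[windows$participant_id == pid, , drop = FALSE]
    ep <- epochs[epochs$participant_id == pid, , drop = FALSE]
    ws <- as.numeric(w$start); we <- as.numeric(w$end)
    t0 <- as.numeric(ep$start)
    idx <- findInterval(t0, ws)
    inside <- idx >= 1L & t0 < we[pmax(idx, 1L)]
    unassigned <- unassigned + sum(!inside)
    ep <- ep[inside, , drop = FALSE]
    idx <- idx[inside]
    wrow <- which(windows$participant_id == pid)
    for (j in seq_len(nrow(w))) {
      e <- ep[idx == j, , drop = FALSE]
      mins <- vapply(classes, function(cl)
        sum(e$duration_s[e$behavior == cl]) / 60, numeric(1))
      covered <- sum(mins)
      rows[[wrow[j]]] <-
        data.frame(participant_id = pid,
                   day_index = w$day_index[j],
                   day_type = w$day_type[j],
                   start = w$start[j],
                   as.list(mins),
                   covered_min = covered,
                   partial = w$partial[j],
                   complete = !w$partial[j] &&
                     abs(covered - DAY_MIN) <= coverage_tol_min,
                   stringsAsFactors = FALSE)
    }
  }
  if (unassigned > 0L)
    warning(sprintf("%d epoch(s) fell outside every day window and were dropped",
                    unassigned), call. = FALSE)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Per-participant day-type summaries with inclusion rules
#'
#' Computes, for each participant, the arithmetic mean minutes per
#' behaviour over the valid days of each day type, and applies the
#' wear-day inclusion rule: at least `min_wear_days` valid days including
#' at least one workday and one leisure day. Partial edge windows are
#' excluded from the means by default, as per-day averages presuppose
#' whole days; days whose epochs cover less than `min_coverage_min` are
#' likewise not counted as wear days.
#'
#' @param days per-day table from [aggregate_timeuse()].
#' @param min_wear_days minimum number of valid days (default 3).
#' @param min_coverage_min minimum covered minutes for a valid day.
#' @param include_partial also count partial edge windows.
#' @return data.frame with one row per participant: day counts, per-
#'   day-type behaviour means (`sb_workday`, ..., `sleep_leisure`),
#'   `included` and `exclusion_reason` (`"none"` or
#'   `"insufficient_days"`).
#' @export
summarize_participants <- function(days, min_wear_days = 3,
                                   min_coverage_min = 1380,
                                   include_partial = FALSE) {
  keep <- days$covered_min >= min_coverage_min
  if (!include_partial) keep <- keep & !days$partial
  days <- days[keep, , drop = FALSE]
  ids <- unique(days$participant_id)
  rows <- lapply(ids, function(pid) {
    d <- days[days$participant_id == pid, , drop = FALSE]
    n_work <- sum(d$day_type == "workday")
    n_leis <- sum(d$day_type == "leisure")
    n_wear <- n_work + n_leis
    means <- unlist(lapply(DAY_TYPES, function(dt) {
      dd <- d[d$day_type == dt, BEHAVIORS, drop = FALSE]
      m <- if (nrow(dd)) colMeans(dd) else rep(NA_real_, length(BEHAVIORS))
      setNames(m, paste0(BEHAVIORS, "_", dt))
    }))
    included <- n_wear >= min_wear_days && n_work >= 1 && n_leis >= 1
    data.frame(participant_id = pid,
               n_workdays = n_work, n_leisure_days = n_leis,
               n_wear_days = n_wear,
               as.list(means),
               included = included,
               exclusion_reason = if (included) "none" else
                 "insufficient_days",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
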