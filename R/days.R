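#' Segment a recording into 24-hour workday and leisure-day windows
#'
#' A workday is 24 h spent at the company, from arrival to departure; a
#' leisure day is 24 h spent outside it, from departure until the next
#' arrival. Each roster interval is cut into consecutive 24-hour windows
#' anchored at its start; a remainder shorter than 24 h becomes a flagged
#' partial window. Time not covered by any roster interval is leisure; an
#' empty roster makes the whole recording leisure, with a warning.
#' Windows are half-open `[start, start + 24 h)`.
#'
#' @param epochs epoch table (used for the recording span per participant).
#' @param roster data.frame `participant_id`, `arrival`, `departure`
#'   (POSIXct); intervals must be non-overlapping with arrival < departure.
#' @param day_min window length in minutes (24 h).
#' @return data.frame with one row per window: `participant_id`,
#'   `day_index`, `day_type` (`"workday"`/`"leisure"`), `start`, `end`
#'   (POSIXct) and `partial` (window shorter than `day_min`).
#' @export
label_days <- function(epochs, roster, day_min = DAY_MIN) {
  stopifnot(all(c("participant_id", "start") %in% names(epochs)))
  if (!is.null(roster) && nrow(roster)) {
    need <- c("participant_id", "arrival", "departure")
    miss <- setdiff(need, names(roster))
    if (length(miss))
      stop("roster is missing column(s): ", paste(miss, collapse = ", "))
    if (any(as.numeric(roster$departure) <= as.numeric(roster$arrival)))
      stop("roster intervals must have arrival < departure")
  }
  day_s <- day_min * 60
  out <- list()
  for (pid in unique(epochs$participant_id)) {
    ep <- epochs[epochs$participant_id == pid, , drop = FALSE]
    span0 <- min(as.numeric(ep$start))
    span1 <- max(as.numeric(ep$start) +
                   if ("duration_s" %in% names(ep)) ep$duration_s else 0)
    r <- if (is.null(roster)) roster[0, ] else
      roster[roster$participant_id == pid, , drop = FALSE]
    if (nrow(r) == 0L) {
      warning(sprintf(
        "participant %s has no roster intervals; all days labelled leisure",
        pid), call. = FALSE)
      segs <- data.frame(s = span0, e = span1, type = "leisure")
    } else {
      r <- r[order(r$arrival), , drop = FALSE]
      a <- as.numeric(r$arrival); d <- as.numeric(r$departure)
      if (nrow(r) > 1L && any(a[-1L] < d[-length(d)]))
        stop(sprintf("overlapping roster intervals for participant %s", pid))
      # walk the recording span, alternating outside/inside company
      segs <- list(); t <- span0
      for (k in seq_along(a)) {
        if (a[k] >= span1) break
        if (d[k] <= span0) next
        if (a[k] > t)
          segs[[length(segs) + 1L]] <-
            data.frame(s = t, e = min(a[k], span1), type = "leisure")
        segs[[length(segs) + 1L]] <-
          data.frame(s = max(a[k], span0), e = min(d[k], span1),
                     type = "workday")
        t <- max(t, min(d[k], span1))
      }
      if (t < span1)
        segs[[length(segs) + 1L]] <-
          data.frame(s = t, e = span1, type = "leisure")
      segs <- do.call(rbind, segs)
      segs <- segs[segs$e > segs$s, , drop = FALSE]
    }
    # cut each contiguous segment into 24 h windows anchored at its start
    wins <- list()
    for (k in seq_len(nrow(segs))) {
      # 1 s tolerance: POSIXct doubles cannot represent sub-second offsets
      # at epoch-time magnitudes, so exact 24 h segments must not spill
      # into a ghost zero-length window
      starts <- seq(segs$s[k], segs$e[k] - 1, by = day_s)
      ends <- pmin(starts + day_s, segs$e[k])
      wins[[k]] <- data.frame(s = starts, e = ends, type = segs$type[k])
    }
    wins <- do.call(rbind, wins)
    wins <- wins[order(wins$s), , drop = FALSE]
    out[[pid]] <- data.frame(
      participant_id = pid,
      day_index = seq_len(nrow(wins)),
      day_type = wins$type,
      start = as.POSIXct(wins$s, origin = "1970-01-01", tz = "UTC"),
      end = as.POSIXct(wins$e, origin = "1970-01-01", tz = "UTC"),
      partial = (wins$e - wins$s) < day_s - 1e-6,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
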