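#' Apply the participant exclusion cascade
#'
#' Reproduces the staged cohort-selection flow of occupational
#' accelerometer studies: starting from all regular employees, remove (in
#' order) day workers, non-consenters, participants who received but did
#' not wear the device, those without a periodic health examination, and
#' finally those with fewer than `min_wear_days` valid wear days or
#' without at least one workday and one leisure day. Stage counts depend
#' on the order (a participant failing two criteria is counted at the
#' first); the final included set does not.
#'
#' @param status data.frame with columns `participant_id`,
#'   `is_day_worker`, `consented`, `wore_device`, `has_exam` (logical),
#'   and either wear-count columns `n_wear_days`, `n_workdays`,
#'   `n_leisure_days` or a `summaries` table supplying them.
#' @param summaries optional output of [summarize_participants()]; when
#'   given, wear counts are joined from it (participants absent from it
#'   get zero counts). A participant flagged `wore_device = FALSE` but
#'   present with positive wear days is a contradiction and errors.
#' @param min_wear_days minimum number of valid wear days (default 3).
#' @return an object of class `exclusion_cascade`: list with `stages`
#'   (data.frame stage/excluded/remaining), `included` (ids) and
#'   `n_included`.
#' @export
apply_exclusion_cascade <- function(status, summaries = NULL,
                                    min_wear_days = 3) {
  need <- c("participant_id", "is_day_worker", "consented",
            "wore_device", "has_exam")
  miss <- setdiff(need, names(status))
  if (length(miss))
    stop("status table is missing column(s): ", paste(miss, collapse = ", "))
  if (!is.null(summaries)) {
    i <- match(status$participant_id, summaries$participant_id)
    contradict <- !status$wore_device & !is.na(i) &
      summaries$n_wear_days[i] > 0
    if (any(contradict))
      stop("contradictory flags: wear data present but wore_device = FALSE for ",
           paste(status$participant_id[contradict], collapse = ", "))
    status$n_wear_days <- ifelse(is.na(i), 0L, summaries$n_wear_days[i])
    status$n_workdays <- ifelse(is.na(i), 0L, summaries$n_workdays[i])
    status$n_leisure_days <- ifelse(is.na(i), 0L,
                                    summaries$n_leisure_days[i])
  }
  cnt <- c("n_wear_days", "n_workdays", "n_leisure_days")
  miss <- setdiff(cnt, names(status))
  if (length(miss))
    stop("status table is missing wear-count column(s): ",
         paste(miss, collapse = ", "))

  fails <- list(
    day_worker = status$is_day_worker,
    no_consent = !status$consented,
    not_worn = !status$wore_device,
    no_exam = !status$has_exam,
    insufficient_days = status$n_wear_days < min_wear_days |
      status$n_workdays < 1 | status$n_leisure_days < 1)

  remaining <- rep(TRUE, nrow(status))
  stages <- data.frame(stage = names(fails), excluded = NA_integer_,
                       remaining = NA_integer_)
  for (k in seq_along(fails)) {
    drop <- remaining & fails[[k]]
    stages$excluded[k] <- sum(drop)
    remaining <- remaining & !drop
    stages$remaining[k] <- sum(remaining)
  }
  structure(list(n_total = nrow(status), stages = stages,
                 included = status$participant_id[remaining],
                 n_included = sum(remaining)),
            class = "exclusion_cascade")
}

#' @export
print.exclusion_cascade <- function(x, ...) {
  cat(sprintf("Exclusion cascade: %d assessed, %d included\n",
              x$n_total, x$n_included))
  print(x$stages, row.names = FALSE)
  invisible(x)
}
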