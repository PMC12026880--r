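iso_fmt <- "%Y-%m-%dT%H:%M:%S"

parse_iso <- function(x, what) {
  out <- as.POSIXct(x, format = iso_fmt, tz = "UTC")
  if (any(is.na(out) & !is.na(x)))
    stop(sprintf("unparseable ISO-8601 datetime in column %s", what))
  out
}

check_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")))
  invisible(df)
}

#' Read an epoch CSV
#'
#' Dialect: header `participant_id,start_iso8601,duration_s,state,mets`;
#' UTF-8; `mets` empty for non-wake epochs.
#'
#' @param path file path.
#' @param validate run [validate_epochs()] (default `TRUE`).
#' @return epoch data.frame (see [validate_epochs()]).
#' @export
read_epoch_csv <- function(path, validate = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("participant_id", "start_iso8601", "duration_s",
                      "state", "mets"), "epoch CSV")
  out <- data.frame(participant_id = as.character(df$participant_id),
                    start = parse_iso(df$start_iso8601, "start_iso8601"),
                    duration_s = as.numeric(df$duration_s),
                    state = as.character(df$state),
                    mets = suppressWarnings(as.numeric(df$mets)),
                    stringsAsFactors = FALSE)
  if (validate) out <- validate_epochs(out)
  out
}

#' Write an epoch table in the package's CSV dialect
#' @param epochs epoch data.frame.
#' @param path file path.
#' @export
write_epoch_csv <- function(epochs, path) {
  out <- data.frame(participant_id = epochs$participant_id,
                    start_iso8601 = format(epochs$start, iso_fmt),
                    duration_s = epochs$duration_s,
                    state = epochs$state, mets = epochs$mets)
  write.csv(out, path, row.names = FALSE, na = "")
}

#' Read a work-roster CSV
#'
#' Dialect: `participant_id,arrival_iso8601,departure_iso8601`.
#' @param path file path.
#' @return data.frame `participant_id`, `arrival`, `departure`.
#' @export
read_roster_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("participant_id", "arrival_iso8601",
                      "departure_iso8601"), "roster CSV")
  data.frame(participant_id = as.character(df$participant_id),
             arrival = parse_iso(df$arrival_iso8601, "arrival_iso8601"),
             departure = parse_iso(df$departure_iso8601,
                                   "departure_iso8601"),
             stringsAsFactors = FALSE)
}

#' Write a work-roster CSV
#' @param roster data.frame `participant_id`, `arrival`, `departure`.
#' @param path file path.
#' @export
write_roster_csv <- function(roster, path) {
  out <- data.frame(participant_id = roster$participant_id,
                    arrival_iso8601 = format(roster$arrival, iso_fmt),
                    departure_iso8601 = format(roster$departure, iso_fmt))
  write.csv(out, path, row.names = FALSE)
}

#' Read a cohort-status CSV
#'
#' Dialect: `participant_id,is_day_worker,consented,wore_device,
#' has_exam` plus optional wear-count columns.
#' @param path file path.
#' @return data.frame with logical flag columns.
#' @export
read_status_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("participant_id", "is_day_worker", "consented",
                      "wore_device", "has_exam"), "cohort-status CSV")
  for (cl in c("is_day_worker", "consented", "wore_device", "has_exam"))
    df[[cl]] <- as.logical(df[[cl]])
  df$participant_id <- as.character(df$participant_id)
  df
}

#' Read a per-participant analysis table
#'
#' The join of covariates, outcomes and day-type behaviour means, as
#' produced by the simulate or extract stages.
#' @param path file path.
#' @param require_outcomes outcome columns that must be present
#'   (default none; the fit stage checks per model).
#' @return data.frame.
#' @export
read_participants_csv <- function(path, require_outcomes = character(0)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "age", "alcohol",
            behavior_cols("workday"), behavior_cols("leisure"),
            require_outcomes)
  check_columns(df, need, "participant CSV")
  df
}
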