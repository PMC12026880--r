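#' Validate an epoch-record table
#'
#' Checks the structural invariants of an epoch stream: required columns,
#' strictly positive durations, METs present if and only if the epoch is a
#' wake epoch, known states, and no overlap between epochs of the same
#' participant.
#'
#' @param epochs data.frame with columns `participant_id`, `start`
#'   (POSIXct, timezone-naive local clock), `duration_s` (seconds, > 0),
#'   `state` (one of `"wake"`, `"main_sleep"`, `"nonmain_sleep"`,
#'   `"nonwear"`) and `mets` (non-negative, `NA` unless `state == "wake"`).
#' @param tol_s overlap tolerance in seconds.
#' @return the input, invisibly, sorted by participant and start time.
#' @export
validate_epochs <- function(epochs, tol_s = 1e-6) {
  need <- c("participant_id", "start", "duration_s", "state", "mets")
  miss <- setdiff(need, names(epochs))
  if (length(miss))
    stop("epoch table is missing column(s): ", paste(miss, collapse = ", "))
  if (!inherits(epochs$start, "POSIXct"))
    stop("epoch `start` must be POSIXct")
  if (any(!is.finite(epochs$duration_s)) || any(epochs$duration_s <= 0))
    stop("epoch durations must be positive")
  bad_state <- setdiff(unique(epochs$state), EPOCH_STATES)
  if (length(bad_state))
    stop("unknown epoch state(s): ", paste(bad_state, collapse = ", "))

  wake <- epochs$state == "wake"
  if (any(wake & is.na(epochs$mets))) {
    i <- which(wake & is.na(epochs$mets))[1L]
    stop(sprintf("wake epoch with missing METs: participant %s at %s",
                 epochs$participant_id[i],
                 format(epochs$start[i], "%Y-%m-%dT%H:%M:%S")))
  }
  if (any(!wake & !is.na(epochs$mets))) {
    i <- which(!wake & !is.na(epochs$mets))[1L]
    stop(sprintf("non-wake epoch carries a METs value: participant %s at %s",
                 epochs$participant_id[i],
                 format(epochs$start[i], "%Y-%m-%dT%H:%M:%S")))
  }
  if (any(wake & epochs$mets < 0, na.rm = TRUE))
    stop("negative METs value")

  ord <- order(epochs$participant_id, epochs$start)
  epochs <- epochs[ord, , drop = FALSE]
  t0 <- as.numeric(epochs$start)
  t1 <- t0 + epochs$duration_s
  same <- epochs$participant_id[-1L] == epochs$participant_id[-nrow(epochs)]
  if (nrow(epochs) > 1L) {
    ovl <- same & (t0[-1L] < t1[-nrow(epochs)] - tol_s)
    if (any(ovl)) {
      i <- which(ovl)[1L]
      stop(sprintf("overlapping epochs for participant %s at %s",
                   epochs$participant_id[i + 1L],
                   format(epochs$start[i + 1L], "%Y-%m-%dT%H:%M:%S")))
    }
  }
  invisible(epochs)
}

#' Classify epochs into behaviour categories
#'
#' Wake epochs are classified by METs cut-points: SB for METs in
#' `[0, sb_max]`, LPA in `(sb_max, mvpa_min)`, MVPA in `[mvpa_min, Inf)`.
#' Main-sleep epochs become the `sleep` behaviour; non-main sleep and
#' non-wear pass through unchanged and are never counted as sleep or SB.
#'
#' The defaults encode the conventional adult cut-points: SB at most 1.5
#' METs, MVPA at 3 METs or more, LPA between. The bands are continuous
#' half-open intervals, so e.g. METs 1.55 is LPA.
#'
#' @param epochs validated epoch table (see [validate_epochs()]).
#' @param sb_max upper METs bound (inclusive) of sedentary behaviour.
#' @param mvpa_min lower METs bound (inclusive) of MVPA.
#' @param validate run [validate_epochs()] first (default `TRUE`).
#' @return the epoch table with an added `behavior` column taking values
#'   in `c("sb","lpa","mvpa","sleep","nonmain_sleep","nonwear")`.
#' @export
classify_epochs <- function(epochs, sb_max = 1.5, mvpa_min = 3.0,
                            validate = TRUE) {
  if (validate) epochs <- validate_epochs(epochs)
  stopifnot(sb_max < mvpa_min)
  behavior <- character(nrow(epochs))
  wake <- epochs$state == "wake"
  m <- epochs$mets[wake]
  behavior[wake] <- ifelse(m <= sb_max, "sb",
                           ifelse(m < mvpa_min, "lpa", "mvpa"))
  behavior[epochs$state == "main_sleep"] <- "sleep"
  behavior[epochs$state == "nonmain_sleep"] <- "nonmain_sleep"
  behavior[epochs$state == "nonwear"] <- "nonwear"
  epochs$behavior <- behavior
  epochs
}

#' Classify METs/state vectors (scalar form of [classify_epochs()])
#'
#' @param mets METs values (`NA` for non-wake epochs).
#' @param state epoch states.
#' @inheritParams classify_epochs
#' @return character vector of behaviour categories.
#' @export
classify_epoch <- function(mets, state = "wake", sb_max = 1.5,
                           mvpa_min = 3.0) {
  n <- max(length(mets), length(state))
  df <- data.frame(participant_id = "x",
                   start = as.POSIXct("2018-01-01", tz = "UTC") +
                     seq_len(n) * 60,
                   duration_s = 60,
                   state = rep_len(state, n),
                   mets = rep_len(mets, n))
  classify_epochs(df, sb_max = sb_max, mvpa_min = mvpa_min)$behavior
}
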