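#' Declare a single-factor or isotemporal substitution model
#'
#' An isotemporal substitution (IS) model regresses a risk factor on all
#' behaviours except the reference plus total behaviour time; each
#' included behaviour's coefficient is the effect of reallocating
#' `delta` minutes from the reference to that behaviour. A single-factor
#' model regresses on one focal behaviour plus total time; the sum of the
#' two coefficients is the effect of adding `delta` minutes of the focal
#' behaviour.
#'
#' @param family `"isotemporal"` or `"single_factor"`.
#' @param outcome one of [OUTCOMES].
#' @param day_type `"workday"` or `"leisure"`.
#' @param reference reference behaviour (isotemporal only).
#' @param focal focal behaviour (single-factor only).
#' @param delta reallocation unit in minutes (default 30).
#' @param covariates covariate column names (default age and alcohol).
#' @param standardize z-score the outcome and continuous predictors.
#' @param log_outcomes outcomes log-transformed before modelling.
#' @param log_base logarithm base for the transform (default 10).
#' @param conf_level confidence level for Wald intervals.
#' @param alpha significance level (default 0.05).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(family = c("isotemporal", "single_factor"),
                       outcome, day_type = c("workday", "leisure"),
                       reference = "sb", focal = NULL, delta = 30,
                       covariates = c("age", "alcohol"),
                       standardize = TRUE,
                       log_outcomes = LOG_OUTCOMES, log_base = 10,
                       conf_level = 0.95, alpha = 0.05) {
  family <- match.arg(family)
  day_type <- match.arg(day_type)
  stopifnot(is.character(outcome), length(outcome) == 1L,
            delta > 0, conf_level > 0, conf_level < 1)
  if (family == "isotemporal") {
    if (!reference %in% BEHAVIORS)
      stop("reference must be one of: ", paste(BEHAVIORS, collapse = ", "))
  } else {
    if (is.null(focal) || !focal %in% BEHAVIORS)
      stop("focal must be one of: ", paste(BEHAVIORS, collapse = ", "))
  }
  structure(list(family = family, outcome = outcome, day_type = day_type,
                 reference = if (family == "isotemporal") reference else NA,
                 focal = if (family == "single_factor") focal else NA,
                 delta = delta, covariates = covariates,
                 standardize = standardize, log_outcomes = log_outcomes,
                 log_base = log_base, conf_level = conf_level,
                 alpha = alpha),
            class = "model_spec")
}
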