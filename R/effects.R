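#' Substitution effect from a fitted isotemporal model
#'
#' The coefficient of `to_behavior` in an isotemporal fit estimates the
#' change in the outcome when `delta` minutes are reallocated from the
#' reference behaviour to `to_behavior`. Substituting the reference into
#' itself is undefined (the effect is identically zero) and errors.
#'
#' @param fit a `sub_fit` with `spec$family == "isotemporal"`.
#' @param to_behavior behaviour receiving the reallocated time.
#' @return one-row data.frame: `from`, `to`, `outcome`, `day_type`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `p`, `significant`.
#' @export
substitution_effect <- function(fit, to_behavior) {
  stopifnot(inherits(fit, "sub_fit"))
  sp <- fit$spec
  if (is.null(sp) || sp$family != "isotemporal")
    stop("substitution_effect requires an isotemporal fit")
  if (identical(to_behavior, sp$reference))
    stop("self-substitution undefined; effect is identically 0")
  if (!to_behavior %in% fit$behavior_terms)
    stop("to_behavior must be one of: ",
         paste(fit$behavior_terms, collapse = ", "))
  row <- fit$coefficients[fit$coefficients$term == to_behavior, ]
  data.frame(from = sp$reference, to = to_behavior, outcome = sp$outcome,
             day_type = sp$day_type, beta = row$estimate, se = row$se,
             ci_low = row$ci_low, ci_high = row$ci_high, p = row$p,
             significant = row$p < sp$alpha, stringsAsFactors = FALSE)
}

#' Effect of adding time to the focal behaviour (single-factor model)
#'
#' In the single-factor model Y ~ B + T + covariates (B the focal
#' behaviour, T total behaviour time), the effect of adding `delta`
#' minutes of B while all other behaviours are held fixed is the sum of
#' the two coefficients, with a linear-combination standard error from
#' the coefficient covariance matrix.
#'
#' @param fit a `sub_fit` with `spec$family == "single_factor"`.
#' @return one-row data.frame: `behavior`, `outcome`, `day_type`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `p`, `significant`.
#' @export
single_factor_effect <- function(fit) {
  stopifnot(inherits(fit, "sub_fit"))
  sp <- fit$spec
  if (is.null(sp) || sp$family != "single_factor")
    stop("single_factor_effect requires a single-factor fit")
  terms <- fit$coefficients$term
  i <- match(sp$focal, terms); j <- match("total", terms)
  est <- fit$coefficients$estimate[i] + fit$coefficients$estimate[j]
  se <- sqrt(fit$vcov[i, i] + fit$vcov[j, j] + 2 * fit$vcov[i, j])
  tq <- qt(1 - (1 - sp$conf_level) / 2, fit$df_residual)
  p <- if (se == 0) as.numeric(est != 0) else
    2 * pt(-abs(est / se), fit$df_residual)
  data.frame(behavior = sp$focal, outcome = sp$outcome,
             day_type = sp$day_type, beta = est, se = se,
             ci_low = est - tq * se, ci_high = est + tq * se, p = p,
             significant = p < sp$alpha, stringsAsFactors = FALSE)
}
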