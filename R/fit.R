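#' Fit a declared model by ordinary least squares
#'
#' Fits OLS with normal-theory (Wald, t-quantile) confidence intervals
#' and two-sided p-values, and computes a variance inflation factor for
#' every non-intercept term from the inverse of the predictor correlation
#' matrix (equal to 1/(1 - R^2) of each predictor regressed on the
#' others). A rank-deficient design is an explicit error naming the
#' collinear columns — e.g. including all four behaviours alongside their
#' total — rather than a silent pseudo-inverse fit.
#'
#' @param design output of [prepare_design()], or a list with elements
#'   `x` (matrix with intercept column) and `y`.
#' @return an object of class `sub_fit`: list with `spec`,
#'   `coefficients` (data.frame term/estimate/se/ci_low/ci_high/p), `n`,
#'   `df_residual`, `vcov`, `vif`, `r_squared`, `sigma`.
#' @export
fit_model <- function(design) {
  X <- design$x; y <- design$y
  n <- nrow(X); p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "),
         " (did you include all behaviours alongside their total?)")
  }
  fit <- lm.fit(X, y)
  df <- n - p
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  V <- sigma2 * solve(crossprod(X))
  est <- fit$coefficients
  se <- sqrt(diag(V))
  conf <- if (!is.null(design$spec)) design$spec$conf_level else 0.95
  tq <- qt(1 - (1 - conf) / 2, df)
  tval <- est / se
  pval <- 2 * pt(-abs(tval), df)
  coefs <- data.frame(term = colnames(X), estimate = unname(est),
                      se = unname(se),
                      ci_low = unname(est - tq * se),
                      ci_high = unname(est + tq * se),
                      p = unname(pval), stringsAsFactors = FALSE)
  # VIF via correlation-matrix inverse (intercept-adjusted identity)
  pred <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  vif <- setNames(diag(solve(cor(pred))), colnames(pred))
  tss <- sum((y - mean(y))^2)
  structure(list(spec = design$spec, coefficients = coefs, n = n,
                 df_residual = df, vcov = V, vif = vif,
                 r_squared = 1 - rss / tss, sigma = sqrt(sigma2),
                 behavior_terms = design$behavior_terms),
            class = "sub_fit")
}

#' @export
print.sub_fit <- function(x, ...) {
  sp <- x$spec
  if (!is.null(sp))
    cat(sprintf("%s model: %s ~ behaviours (%s), n = %d, R^2 = %.3f\n",
                sp$family, sp$outcome, sp$day_type, x$n, x$r_squared))
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat("VIF:", paste(sprintf("%s=%.2f", names(x$vif), x$vif),
                    collapse = ", "), "\n")
  invisible(x)
}

#' Convenience wrapper: prepare and fit in one call
#' @inheritParams prepare_design
#' @inheritParams fit_model
#' @param spec a [model_spec()].
#' @return a `sub_fit` (see [fit_model()]).
#' @export
fit_spec <- function(records, spec) fit_model(prepare_design(records, spec))
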