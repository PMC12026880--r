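#' Build the design matrix and response for a declared model
#'
#' Behaviour minutes are rescaled to `delta`-minute units (minutes /
#' `delta`) before anything else, so unstandardized coefficients are
#' per-`delta`-minute effects. Log-flagged outcomes are transformed
#' (base `spec$log_base`, default 10) and must be strictly positive.
#' With `standardize = TRUE`, the transformed outcome and every
#' continuous predictor are z-scored; binary predictors (all values in
#' {0, 1}) are left on their natural scale. Rows with missing values in
#' any used column are dropped listwise with a message.
#'
#' @param records per-participant table with covariates, outcome columns
#'   and behaviour-mean columns named `<behavior>_<day_type>` (e.g.
#'   `sb_workday`), in minutes.
#' @param spec a [model_spec()].
#' @return list with the design matrix `x` (including an intercept
#'   column), response `y`, `spec`, `n`, `n_dropped` and the names of the
#'   behaviour terms.
#' @export
prepare_design <- function(records, spec) {
  stopifnot(inherits(spec, "model_spec"))
  bcols <- behavior_cols(spec$day_type)
  used <- c(spec$outcome, bcols, spec$covariates)
  miss <- setdiff(used, names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "))

  cc <- complete.cases(records[, used, drop = FALSE])
  n_dropped <- sum(!cc)
  if (n_dropped > 0)
    message(sprintf("prepare_design: dropped %d row(s) with missing values",
                    n_dropped))
  rec <- records[cc, , drop = FALSE]

  y <- rec[[spec$outcome]]
  if (spec$outcome %in% spec$log_outcomes) {
    if (any(y <= 0))
      stop(sprintf("outcome %s is log-transformed but has non-positive values",
                   spec$outcome))
    y <- log(y, base = spec$log_base)
  }

  B <- as.matrix(rec[, bcols, drop = FALSE]) / spec$delta
  colnames(B) <- BEHAVIORS
  total <- rowSums(B)

  if (spec$family == "isotemporal") {
    terms_b <- setdiff(BEHAVIORS, spec$reference)
  } else {
    terms_b <- spec$focal
  }
  X <- cbind(B[, terms_b, drop = FALSE], total = total)
  for (cv in spec$covariates) X <- cbind(X, rec[[cv]])
  colnames(X) <- c(terms_b, "total", spec$covariates)

  n <- nrow(X)
  if (n < ncol(X) + 3L)
    stop(sprintf("too few complete observations (n = %d) for %d predictors",
                 n, ncol(X)))

  is_binary <- apply(X, 2, function(v) all(v %in% c(0, 1)))
  if (spec$standardize) {
    sdy <- sd(y)
    if (sdy == 0) stop("outcome has zero variance; cannot standardize")
    y <- (y - mean(y)) / sdy
    for (j in which(!is_binary)) {
      sdx <- sd(X[, j])
      if (sdx == 0)
        stop(sprintf("predictor %s has zero variance", colnames(X)[j]))
      X[, j] <- (X[, j] - mean(X[, j])) / sdx
    }
  } else {
    zv <- vapply(seq_len(ncol(X)), function(j) sd(X[, j]) == 0, logical(1))
    if (any(zv))
      stop(sprintf("predictor %s has zero variance",
                   paste(colnames(X)[zv], collapse = ", ")))
  }
  X <- cbind("(Intercept)" = 1, X)

  list(x = X, y = y, spec = spec, n = n, n_dropped = n_dropped,
       behavior_terms = terms_b)
}
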