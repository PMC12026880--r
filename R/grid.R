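#' Run the full outcome x day-type x reference analysis grid
#'
#' Fits, for every combination of outcome, day type and reference
#' behaviour, the isotemporal substitution model (yielding one estimate
#' per non-reference behaviour), and for every focal behaviour the
#' single-factor model. Each cell is fitted both unstandardized (per-
#' `delta`-minute raw effects) and fully standardized (z-scored outcome
#' and continuous predictors); because standardization is an affine
#' rescaling, t statistics and p-values agree between the two. Cells
#' that fail (e.g. a zero-variance predictor within a day type) are
#' reported with a diagnostic in `status` without aborting the grid;
#' cells whose largest VIF exceeds `vif_limit` are flagged.
#'
#' @param records per-participant table (see [prepare_design()]).
#' @param outcomes outcomes to model (default all 11).
#' @param day_types day types to model.
#' @param references reference behaviours for the isotemporal family.
#' @param focals focal behaviours for the single-factor family.
#' @param delta reallocation unit in minutes.
#' @param covariates covariate columns.
#' @param log_outcomes outcomes log-transformed before modelling.
#' @param alpha significance level.
#' @param vif_limit acceptable VIF threshold (default 5).
#' @param conf_level confidence level.
#' @return data.frame of class `sub_grid`, long format: `family`,
#'   `outcome`, `day_type`, `from`, `to`, standardized `beta`/`ci_low`/
#'   `ci_high`, raw `beta_raw`/`ci_raw_low`/`ci_raw_high`, `p`,
#'   `significant`, `vif_max`, `vif_ok`, `n`, `status`.
#' @export
run_analysis_grid <- function(records, outcomes = OUTCOMES,
                              day_types = DAY_TYPES,
                              references = BEHAVIORS,
                              focals = BEHAVIORS, delta = 30,
                              covariates = c("age", "alcohol"),
                              log_outcomes = LOG_OUTCOMES,
                              alpha = 0.05, vif_limit = 5,
                              conf_level = 0.95) {
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  fail_row <- function(family, outcome, day_type, from, to, msg)
    data.frame(family = family, outcome = outcome, day_type = day_type,
               from = from, to = to, beta = NA_real_, ci_low = NA_real_,
               ci_high = NA_real_, beta_raw = NA_real_,
               ci_raw_low = NA_real_, ci_raw_high = NA_real_,
               p = NA_real_, significant = NA, vif_max = NA_real_,
               vif_ok = NA, n = NA_integer_,
               status = paste0("failed: ", msg), stringsAsFactors = FALSE)

  for (oc in outcomes) for (dt in day_types) {
    for (ref in references) {
      res <- tryCatch({
        mk <- function(std) model_spec("isotemporal", outcome = oc,
                                       day_type = dt, reference = ref,
                                       delta = delta,
                                       covariates = covariates,
                                       standardize = std,
                                       log_outcomes = log_outcomes,
                                       conf_level = conf_level,
                                       alpha = alpha)
        fr <- suppressMessages(fit_spec(records, mk(FALSE)))
        fs <- suppressMessages(fit_spec(records, mk(TRUE)))
        vmax <- max(fr$vif)
        do.call(rbind, lapply(setdiff(BEHAVIORS, ref), function(to) {
          er <- substitution_effect(fr, to)
          es <- substitution_effect(fs, to)
          data.frame(family = "isotemporal", outcome = oc, day_type = dt,
                     from = ref, to = to, beta = es$beta,
                     ci_low = es$ci_low, ci_high = es$ci_high,
                     beta_raw = er$beta, ci_raw_low = er$ci_low,
                     ci_raw_high = er$ci_high, p = er$p,
                     significant = er$significant, vif_max = vmax,
                     vif_ok = vmax < vif_limit, n = fr$n, status = "ok",
                     stringsAsFactors = FALSE)
        }))
      }, error = function(e)
        fail_row("isotemporal", oc, dt, ref, NA_character_,
                 conditionMessage(e)))
      add(res)
    }
    for (fb in focals) {
      res <- tryCatch({
        mk <- function(std) model_spec("single_factor", outcome = oc,
                                       day_type = dt, focal = fb,
                                       delta = delta,
                                       covariates = covariates,
                                       standardize = std,
                                       log_outcomes = log_outcomes,
                                       conf_level = conf_level,
                                       alpha = alpha)
        fr <- suppressMessages(fit_spec(records, mk(FALSE)))
        fs <- suppressMessages(fit_spec(records, mk(TRUE)))
        er <- single_factor_effect(fr)
        es <- single_factor_effect(fs)
        vmax <- max(fr$vif)
        data.frame(family = "single_factor", outcome = oc, day_type = dt,
                   from = NA_character_, to = fb, beta = es$beta,
                   ci_low = es$ci_low, ci_high = es$ci_high,
                   beta_raw = er$beta, ci_raw_low = er$ci_low,
                   ci_raw_high = er$ci_high, p = er$p,
                   significant = er$significant, vif_max = vmax,
                   vif_ok = vmax < vif_limit, n = fr$n, status = "ok",
                   stringsAsFactors = FALSE)
      }, error = function(e)
        fail_row("single_factor", oc, dt, NA_character_, fb,
                 conditionMessage(e)))
      add(res)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sub_grid", class(out))
  out
}

#' Arrow-style direction summary of a fitted grid
#'
#' Summarizes isotemporal estimates as `"up"` (significant positive),
#' `"down"` (significant negative) or `"ns"`, the compact surface used to
#' report which reallocations matter per day type.
#'
#' @param grid output of [run_analysis_grid()].
#' @param outcomes restrict to these outcomes (default: all in `grid`).
#' @param pairs optional data.frame with columns `from`, `to` (and
#'   optionally `day_type`) restricting the rows.
#' @return data.frame `day_type`, `from`, `to`, `outcome`, `beta`, `p`,
#'   `direction`, `arrow`.
#' @export
direction_summary <- function(grid, outcomes = NULL, pairs = NULL) {
  g <- grid[grid$family == "isotemporal" & grid$status == "ok", ,
            drop = FALSE]
  if (!is.null(outcomes)) g <- g[g$outcome %in% outcomes, , drop = FALSE]
  if (!is.null(pairs)) {
    key_g <- paste(g$from, g$to,
                   if ("day_type" %in% names(pairs)) g$day_type else "")
    key_p <- paste(pairs$from, pairs$to,
                   if ("day_type" %in% names(pairs)) pairs$day_type else "")
    g <- g[key_g %in% key_p, , drop = FALSE]
  }
  direction <- ifelse(!g$significant, "ns",
                      ifelse(g$beta_raw > 0, "up", "down"))
  arrow <- c(up = "\u2191", down = "\u2193", ns = "ns")[direction]
  data.frame(day_type = g$day_type, from = g$from, to = g$to,
             outcome = g$outcome, beta = g$beta, p = g$p,
             direction = direction, arrow = unname(arrow),
             stringsAsFactors = FALSE)
}

#' Compare workday and leisure-day time use (paired Wilcoxon)
#'
#' For each behaviour, reports per-day-type means and SDs and the paired
#' Wilcoxon signed-rank test between the two day types (normal
#' approximation, delegated to [stats::wilcox.test()]). A degenerate
#' comparison (all paired differences zero) is reported with `p = NA`
#' and a note rather than an error.
#'
#' @param records per-participant table with `<behavior>_workday` and
#'   `<behavior>_leisure` columns.
#' @param behaviors behaviours to compare.
#' @return data.frame `behavior`, `n`, `mean_workday`, `sd_workday`,
#'   `mean_leisure`, `sd_leisure`, `statistic`, `p`, `note`.
#' @export
compare_daytypes <- function(records, behaviors = BEHAVIORS) {
  rows <- lapply(behaviors, function(b) {
    w <- records[[paste0(b, "_workday")]]
    l <- records[[paste0(b, "_leisure")]]
    ok <- !is.na(w) & !is.na(l)
    w <- w[ok]; l <- l[ok]
    if (length(w) < 2L)
      stop(sprintf("fewer than 2 complete day-type pairs for %s", b))
    note <- ""
    if (all(w == l)) {
      stat <- 0; p <- NA_real_
      note <- "degenerate: all paired differences zero"
    } else {
      wt <- suppressWarnings(wilcox.test(w, l, paired = TRUE,
                                         exact = FALSE, correct = TRUE))
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    data.frame(behavior = b, n = length(w), mean_workday = mean(w),
               sd_workday = sd(w), mean_leisure = mean(l),
               sd_leisure = sd(l), statistic = stat, p = p, note = note,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
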