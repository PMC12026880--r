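test_that("design matrices have the declared structure", {
  rec <- random_records(40, seed = 11)
  d <- prepare_design(rec, model_spec("isotemporal", "wc", "workday",
                                      reference = "sb",
                                      standardize = FALSE))
  expect_equal(colnames(d$x),
               c("(Intercept)", "lpa", "mvpa", "sleep", "total",
                 "age", "alcohol"))
  # delta scaling: 600 min at delta = 30 is 20 units
  rec$lpa_workday[1] <- 600
  d2 <- prepare_design(rec, model_spec("isotemporal", "wc", "workday",
                                       reference = "sb",
                                       standardize = FALSE))
  expect_equal(d2$x[1, "lpa"], 20, ignore_attr = TRUE)
  # single-factor design
  d3 <- prepare_design(rec, model_spec("single_factor", "wc", "workday",
                                       focal = "mvpa",
                                       standardize = FALSE))
  expect_equal(colnames(d3$x),
               c("(Intercept)", "mvpa", "total", "age", "alcohol"))
})

test_that("log-flagged outcomes are transformed base-10 before modelling", {
  rec <- random_records(40, seed = 12)
  rec$tg <- 100
  d <- prepare_design(rec, model_spec("isotemporal", "tg", "workday",
                                      standardize = FALSE))
  expect_equal(unique(d$y), 2)
  rec$tg[1] <- 0
  expect_error(prepare_design(rec, model_spec("isotemporal", "tg",
                                              "workday")),
               "non-positive")
})

test_that("rank deficiency is an explicit error naming collinear columns", {
  rec <- random_records(50, seed = 13)
  d <- prepare_design(rec, model_spec("isotemporal", "wc", "workday",
                                      standardize = FALSE))
  # re-introduce the reference so total = sum of all four behaviours
  X <- cbind(d$x, sb = rowSums(d$x[, c("total"), drop = FALSE]) -
               rowSums(d$x[, c("lpa", "mvpa", "sleep"), drop = FALSE]))
  expect_error(fit_model(list(x = X, y = d$y, spec = d$spec)),
               "collinear")
})

test_that("noise-free synthetic data is recovered exactly", {
  set.seed(21)
  n <- 60
  rec <- random_records(n, seed = 21)
  g <- c(sb = 0.3, lpa = -0.5, mvpa = -1.2, sleep = 0.1)
  rec$wc <- 80 +
    as.matrix(rec[, behavior_cols("workday")]) %*% g / 30 +
    0.2 * rec$age + 1.5 * rec$alcohol
  rec$wc <- as.vector(rec$wc)
  f <- fit_spec(rec, model_spec("isotemporal", "wc", "workday",
                                reference = "sb", standardize = FALSE))
  cf <- setNames(f$coefficients$estimate, f$coefficients$term)
  expect_equal(cf[["lpa"]], g[["lpa"]] - g[["sb"]], tolerance = 1e-8)
  expect_equal(cf[["mvpa"]], g[["mvpa"]] - g[["sb"]], tolerance = 1e-8)
  expect_equal(cf[["total"]], g[["sb"]], tolerance = 1e-8)
  expect_equal(cf[["age"]], 0.2, tolerance = 1e-8)
  expect_gt(f$r_squared, 0.999999)
})

test_that("substitution effects: self-substitution errors, antisymmetry holds", {
  rec <- random_records(80, seed = 31)
  f_sb <- fit_spec(rec, model_spec("isotemporal", "wc", "workday",
                                   reference = "sb",
                                   standardize = FALSE))
  expect_error(substitution_effect(f_sb, "sb"), "self-substitution")
  for (b in c("lpa", "mvpa", "sleep")) {
    f_b <- fit_spec(rec, model_spec("isotemporal", "wc", "workday",
                                    reference = b, standardize = FALSE))
    expect_equal(substitution_effect(f_sb, b)$beta,
                 -substitution_effect(f_b, "sb")$beta,
                 tolerance = 1e-8)
  }
})

test_that("delta-linearity: unstandardized effect at 60 min is twice that at 30", {
  rec <- random_records(80, seed = 32)
  b30 <- substitution_effect(
    fit_spec(rec, model_spec("isotemporal", "wc", "workday",
                             delta = 30, standardize = FALSE)), "lpa")$beta
  b60 <- substitution_effect(
    fit_spec(rec, model_spec("isotemporal", "wc", "workday",
                             delta = 60, standardize = FALSE)), "lpa")$beta
  expect_equal(b60, 2 * b30, tolerance = 1e-10)
})

test_that("standardized effects are invariant to outcome units", {
  rec <- random_records(80, seed = 33)
  rec2 <- rec
  rec2$wc <- rec$wc * 10 + 100   # affine unit change
  b1 <- substitution_effect(
    fit_spec(rec, model_spec("isotemporal", "wc", "workday")), "lpa")
  b2 <- substitution_effect(
    fit_spec(rec2, model_spec("isotemporal", "wc", "workday")), "lpa")
  expect_equal(b1$beta, b2$beta, tolerance = 1e-10)
  expect_equal(b1$p, b2$p, tolerance = 1e-10)
})

test_that("single-factor effect equals the reparameterized focal coefficient", {
  rec <- random_records(90, seed = 41)
  for (b in BEHAVIORS) {
    f <- fit_spec(rec, model_spec("single_factor", "dbp", "leisure",
                                  focal = b, standardize = FALSE))
    e <- single_factor_effect(f)
    other <- rowSums(rec[, behavior_cols("leisure")]) -
      rec[[paste0(b, "_leisure")]]
    alt <- lm(rec$dbp ~ I(rec[[paste0(b, "_leisure")]] / 30) +
                I(other / 30) + rec$age + rec$alcohol)
    expect_equal(e$beta, unname(coef(alt)[2]), tolerance = 1e-8)
  }
})

test_that("all-zero response gives a zero single-factor effect with symmetric CI", {
  rec <- random_records(50, seed = 42)
  rec$sbp <- 0
  f <- fit_spec(rec, model_spec("single_factor", "sbp", "workday",
                                focal = "sb", standardize = FALSE))
  e <- single_factor_effect(f)
  expect_equal(e$beta, 0, tolerance = 1e-12)
  expect_equal(e$ci_low, -e$ci_high, tolerance = 1e-12)
})

test_that("VIFs are at least 1 and match the auxiliary-regression definition", {
  rec <- random_records(70, seed = 51)
  f <- fit_spec(rec, model_spec("isotemporal", "hdl", "workday",
                                standardize = FALSE))
  expect_true(all(f$vif >= 1))
  d <- prepare_design(rec, model_spec("isotemporal", "hdl", "workday",
                                      standardize = FALSE))
  X <- d$x[, colnames(d$x) != "(Intercept)"]
  oracle <- vapply(colnames(X), function(j) {
    r2 <- summary(lm(X[, j] ~ X[, colnames(X) != j]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  expect_equal(f$vif, oracle, tolerance = 1e-10)
})

test_that("the analysis grid has the expected shape and survives bad cells", {
  rec <- random_records(60, seed = 61)
  g <- run_analysis_grid(rec, outcomes = OUTCOMES, references = "sb",
                         focals = character(0))
  # 11 outcomes x 2 day types x 3 to-behaviours for one reference
  expect_equal(sum(g$family == "isotemporal" & g$status == "ok"), 66L)

  rec$ldl <- NA_real_                     # an all-missing outcome
  rec$mvpa_leisure <- 30                  # a zero-variance predictor
  g2 <- run_analysis_grid(rec, outcomes = c("wc", "ldl"),
                          references = c("sb"), focals = "sb")
  ldl <- g2[g2$outcome == "ldl", ]
  expect_true(all(ldl$status != "ok"))
  wc_work <- g2[g2$outcome == "wc" & g2$day_type == "workday", ]
  expect_true(all(wc_work$status == "ok"))
  wc_leis <- g2[g2$outcome == "wc" & g2$day_type == "leisure" &
                  g2$family == "isotemporal", ]
  expect_true(all(grepl("zero variance", wc_leis$status)))
  # the single-factor sb cell does not touch the degenerate predictor
  wc_leis_sf <- g2[g2$outcome == "wc" & g2$day_type == "leisure" &
                     g2$family == "single_factor", ]
  expect_true(all(wc_leis_sf$status == "ok"))
})

test_that("direction summary maps signs and significance to arrows", {
  grid <- data.frame(
    family = "isotemporal", outcome = c("wc", "tg", "ast"),
    day_type = "workday", from = "sb", to = "lpa",
    beta = c(-0.3, 0.4, 0.05), beta_raw = c(-0.6, 0.9, 0.1),
    p = c(0.01, 0.002, 0.7), significant = c(TRUE, TRUE, FALSE),
    status = "ok", stringsAsFactors = FALSE)
  ds <- direction_summary(grid)
  expect_equal(ds$direction, c("down", "up", "ns"))
  expect_equal(ds$arrow, c("↓", "↑", "ns"))
})

test_that("paired Wilcoxon statistic matches a hand-ranked 6-pair example", {
  # differences 1, -2, 3, -4, 5, 6 -> |d| ranks 1..6,
  # V = sum of ranks of positive differences = 1 + 3 + 5 + 6 = 15
  w <- c(11, 8, 13, 6, 15, 16)
  l <- c(10, 10, 10, 10, 10, 10)
  rec <- data.frame(sb_workday = w, sb_leisure = l)
  got <- compare_daytypes(rec, behaviors = "sb")
  expect_equal(got$statistic, 15)
  expect_equal(got$n, 6L)
})

test_that("degenerate day-type comparison is reported, not an error", {
  rec <- data.frame(sb_workday = c(1, 2, 3), sb_leisure = c(1, 2, 3))
  got <- compare_daytypes(rec, behaviors = "sb")
  expect_true(is.na(got$p))
  expect_match(got$note, "degenerate")
  expect_error(compare_daytypes(data.frame(sb_workday = 1,
                                           sb_leisure = 1),
                                behaviors = "sb"),
               "fewer than 2")
})

test_that("day-type differences in sleep and LPA are detected with high power", {
  # cohorts at the default behaviour-time parameters, n = 66
  plan <- cohort_plan()
  nrep <- 200
  hits <- c(sleep = 0L, lpa = 0L)
  for (r in seq_len(nrep)) {
    co <- generate_cohort(plan, n = 66, seed = 40000 + r)
    cmp <- compare_daytypes(co$records, behaviors = c("sleep", "lpa"))
    hits <- hits + setNames(cmp$p < 0.001, cmp$behavior)[names(hits)]
  }
  expect_gte(hits[["sleep"]] / nrep, 0.95)
  expect_gte(hits[["lpa"]] / nrep, 0.95)
})
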