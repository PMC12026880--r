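# shiftsub

Time-use extraction and isotemporal substitution modelling for
night-shift-worker cohorts.

Night-shift workers alternate between two kinds of 24-hour day —
workdays spent entirely at the company and leisure days entirely
outside it — and the two carry very different movement compositions
(long light activity and short sleep at work, the reverse at home).
Because the day is a closed 1440-minute budget, asking whether "more
MVPA" or "more sleep" relates to cardiovascular risk only makes sense
as a *reallocation* question. `shiftsub` is for epidemiologists and
occupational-health researchers who have epoch-level accelerometer
exports, a work roster and health-examination outcomes, and want the
standard answer to that question, separately by day type.

## What it computes

Wake epochs are classified by METs cut-points (SB ≤ 1.5, LPA in
(1.5, 3), MVPA ≥ 3; only main sleep counts as sleep), recordings are cut
into 24-h workday/leisure windows from the roster (arrival → departure
= workday), and per-day-type means are computed under wear rules
(≥ 3 valid days, ≥ 1 of each day type) and a staged exclusion cascade.

For outcome *Y*, behaviours *B<sub>k</sub>* in Δ-minute units
(Δ = 30 by default) and total time *T* = Σ *B<sub>k</sub>*:

* **Isotemporal substitution model** (reference *A* dropped):
  *Y* = β₀ + Σ<sub>k≠A</sub> β<sub>k</sub>B<sub>k</sub> + β<sub>T</sub>T
  + β<sub>c</sub>ᵀ**c** + ε.  β<sub>k</sub> estimates the change in *Y*
  when Δ minutes move from *A* to *k*; equivalently
  β<sub>k</sub> = γ<sub>k</sub> − γ<sub>A</sub> in the all-behaviours
  partition model.
* **Single-factor model**: *Y* = β₁B + β₂T + …; β₁ + β₂ is the effect
  of adding Δ minutes of *B*.

Estimates come with Wald 95% CIs, p-values, VIF diagnostics
(threshold 5), base-10 log transforms for TG/AST/ALT/γ-GTP, and both
fully standardized and raw per-Δ-minute scales. A synthetic-cohort
generator (shift calendars, 1-min epoch streams, outcomes with planted
substitution effects and known ground truth) backs every test.

## Worked example

```r
library(shiftsub)

plan <- cohort_plan()                       # the default stated world
co   <- generate_cohort(plan, n = 66, seed = 2024)

compare_daytypes(co$records)
#>   behavior mean_workday sd_workday mean_leisure sd_leisure        p
#> 1       sb        337.6       77.9        370.9       56.1 1.21e-02
#> 2      lpa        586.8       96.2        213.1       38.6 1.68e-12
#> 3     mvpa         65.9       25.7         28.6       10.2 7.83e-12
#> 4    sleep        299.2       60.6        561.5       66.7 1.68e-12
```

The paired Wilcoxon tests confirm what the calendar builds in: on
workdays this cohort moves lightly for ~10 h and sleeps under 5 h; on
leisure days sleep nearly doubles. Now one substitution estimate —
reallocating 30 min of workday SB to LPA, with waist circumference as
outcome:

```r
f <- fit_spec(co$records,
              model_spec("isotemporal", "wc", "workday", reference = "sb"))
substitution_effect(f, "lpa")
#>   from  to outcome day_type   beta    se ci_low ci_high    p significant
#> 1   sb lpa      wc  workday -0.242 0.178 -0.599   0.115 0.18       FALSE
```

The standardized effect is negative (−0.242 SD of WC per 30 min moved
from SB to LPA) but its CI crosses zero: at n = 66 with realistic noise
a true planted effect of this size is frequently not significant —
which is exactly the power situation such cohorts face. The acceptance
suite verifies the estimator itself by identity (to 1e-8) and by
coverage/bias over 500 replicates, and reproduces the full planted
direction pattern at n = 1000.

The whole grid and its arrow summary:

```r
grid <- run_analysis_grid(co$records, outcomes = c("wc", "tg", "ast"),
                          references = c("sb", "sleep"))
direction_summary(grid)      # "up" / "down" / "ns" per reallocation cell
```

## Command line

```sh
Rscript -e 'shiftsub::cli_main()' simulate --seed 1 --out-dir sim/
Rscript -e 'shiftsub::cli_main()' extract --epochs sim/epochs.csv \
    --roster sim/roster.csv --status sim/status.csv --out-dir ext/
Rscript -e 'shiftsub::cli_main()' fit --participants sim/participants.csv \
    --out-dir fit/
Rscript -e 'shiftsub::cli_main()' report --estimates fit/estimates.csv \
    --out-dir rep/
```

Each stage validates its CSV dialect (errors name the missing column),
writes a `run_manifest.json` (config snapshot, input digests, seed,
timings, version) and exits non-zero on failure. `--config file.json`
overrides defaults with strict unknown-key rejection.

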