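---
title: "Time-use extraction and isotemporal substitution modelling for night-shift cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-use extraction and isotemporal substitution modelling for night-shift cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Night-shift workers split their lives into two very different kinds of
24-hour day: workdays spent entirely at the company (night work,
in-company free time, day work) and leisure days spent entirely outside
it. Because a day has a fixed budget of 1440 minutes, time spent on one
behaviour — sedentary behaviour (SB), light physical activity (LPA),
moderate-to-vigorous physical activity (MVPA) or main sleep — can only
increase at the expense of another. `shiftsub` implements the full
analysis chain for asking how *reallocating* time between behaviours,
separately by day type, is associated with cardiovascular disease (CVD)
risk factors: epoch-level accelerometer classification, day-type
segmentation, per-participant aggregation with wear-day rules, and the
two regression families that respect the time budget.

## Time-use extraction

Wake epochs are classified by METs cut-points: SB at or below 1.5 METs,
MVPA at or above 3 METs, LPA between. Because METs are continuous, the
conventional band labels (1.6–2.9 for LPA) leave gaps at (1.5, 1.6) and
(2.9, 3.0); we close them with continuous half-open bands
SB = [0, 1.5], LPA = (1.5, 3.0), MVPA = [3, ∞), which agree with the
labels at every labelled value. Only *main* sleep (the primary
bedtime-to-waking bout, scored upstream by the device software) counts
as the sleep behaviour; non-main sleep may include supine stillness
without sleep and is carried separately, never as sleep or SB.

A workday is the 24 h from company arrival to departure; a leisure day
is 24 h outside, anchored at the departure instant. Roster intervals
longer than 24 h split into consecutive 24-hour windows from arrival,
with a flagged partial remainder; time not covered by any roster
interval is leisure; an empty roster makes the whole recording leisure,
with a warning. All intervals are half-open on the local clock,
timezone-naive. Aggregation sums exact epoch durations (2-s wake and
2-min sleep epochs mix freely; no resampling). Partial edge windows are
**excluded** from per-day-type means by default — per-day averages
presuppose whole days — with `include_partial = TRUE` to override; this
was left open by the source methodology and is our choice.

Participants are retained when they have at least 3 valid wear days
including at least one workday and one leisure day. The staged
exclusion cascade (day workers, consent, device not worn, no health
examination, insufficient days) reports per-stage counts; counts depend
on stage order but the final included set provably does not.

## The regression models

For outcome $Y$, behaviours $B_k$ in $\Delta$-minute units (default
$\Delta = 30$ min) and total behaviour time $T = \sum_k B_k$, the
isotemporal substitution (IS) model with reference $A$ is

$$Y = \beta_0 + \sum_{k \ne A} \beta_k B_k + \beta_T T +
  \boldsymbol\beta_c^\top \mathbf{c} + \varepsilon,$$

with covariates $\mathbf{c}$ = age and alcohol status. Because $T$ is
held fixed, $\beta_k$ is the expected change in $Y$ when $\Delta$
minutes move from $A$ to $k$, and $\beta_T$ carries the reference's own
association. Equivalently, in the partition model
$Y = \gamma_0 + \sum_k \gamma_k B_k + \ldots$ (no total term),
$\beta_k = \gamma_k - \gamma_A$ and $\beta_T = \gamma_A$ — an exact
linear-algebra identity that the test suite verifies to $10^{-8}$, along
with the antisymmetry $\beta_{A\to B} = -\beta_{B\to A}$.

The single-factor model $Y = \beta_1 B + \beta_2 T + \ldots$ measures
one behaviour without reallocation; $\beta_1 + \beta_2$ is the effect of
*adding* $\Delta$ minutes of $B$ (other behaviours fixed), with a
linear-combination standard error. It equals the focal coefficient of
the regression on $\{B,\, T - B\}$, the second identity the tests pin.

TG and the liver enzymes (AST, ALT, γ-GTP) are log-transformed before
modelling. The base is not dictated by the methodology we follow; the
printed characteristic values (logTG ≈ 2.0 at ~100 mg/dL, logAST ≈ 1.4
at ~25 U/L) are consistent with base 10, so base 10 is the default and
it is configurable. Transformation happens before standardization.

**Standardization.** "Standardized coefficients for a 30-minute
reallocation" is internally ambiguous: full z-scoring absorbs the
30-minute unit. We emit both: the default `beta` column is the fully
standardized coefficient (z-scored outcome and continuous predictors;
binary alcohol untouched), and `beta_raw` is the unstandardized
per-$\Delta$-minute effect with its own CI. Standardization is affine,
so t statistics and p-values coincide; the raw scale obeys
$\Delta$-linearity (the 60-min effect is twice the 30-min effect), and
the standardized scale is invariant to outcome units.

Inference is OLS with normal-theory (t) Wald CIs at 95% and per-cell
$p < 0.05$, no multiple-testing correction — mirroring the analysis
style this package reproduces, and a documented limitation. VIFs come
from the inverse predictor correlation matrix (identical to 1/(1−R²)
of each auxiliary regression, checked to $10^{-10}$); cells with
VIF ≥ 5 are flagged. A rank-deficient design (e.g. all four behaviours
plus their total) is an explicit error naming the collinear columns,
never a silent pseudo-inverse fit. Missing data are handled by listwise
deletion per model with logged counts; degenerate grid cells
(zero-variance predictor within a day type) are skipped with a
diagnostic rather than aborting the grid.

## The synthetic cohort

The generator's defaults are the stated world of the study design it
emulates: 157 employees of whom 24 day workers, then 2 / 44 / 15 / 6
staged exclusions leaving 66 men; arrival 18:30, night work to 04:00,
in-company free time 04:00–10:00 (capsule-bed sleep), day work
10:00–18:30, departure 18:30; alternating work/leisure days thinned to
10.8 (SD 2.0) shifts per 30-day month; wear protocol of 6.2 (SD 1.3)
days with 1.9 workdays and 4.2 leisure days; behaviour-time means/SDs
per day type (e.g. workday LPA 599.3 (127.6) min, workday sleep 294.7
(68.4) min, leisure sleep 549.3 (119.3) min); age 40.2 (9.9), 59%
drinkers; outcome marginals such as WC 84.8 (9.3) cm and logTG 2.0
(0.3).

Daily minutes are sequential truncated-normal draws in the order sleep,
MVPA, LPA, SB, each bounded at 0 and the day's remaining budget, with
the slack emitted as non-wear — only marginal means/SDs are stated
anywhere, so behaviours are drawn independently (configurable only by
replacing the draw). A consequence worth knowing: on workdays the
budget binds for roughly a quarter of days, so realized workday SB runs
about 35 minutes below its nominal mean (the other behaviours, drawn
earlier, are unaffected); the fidelity tests check SB against the
analytic truncated mean rather than pretending otherwise. Epoch
streams are a uniform 1-minute grid (the mixed 2-s/2-min device grid is
an extraction concern, not a generation one), with main sleep placed as
one block at 04:00 on workdays and midnight on leisure days, and wake
METs drawn uniformly inside each behaviour's band — so extraction
round-trips exactly.

Outcomes are linear in the per-day-type behaviour means
($\Delta$-minute units) with partition-model coefficients $\gamma$,
Gaussian noise at the marginal SDs, and intercepts chosen to centre
each outcome on its marginal mean; log-flagged outcomes are generated
on the log10 scale and exponentiated. The default $\gamma$ plants
exactly three non-zero entries (workday LPA → WC −0.8 cm/30 min;
workday sleep → logTG −0.05/30 min; leisure MVPA → logAST −0.04/30
min), which makes exactly five reallocation contrasts non-null on the
reporting surface and all others zero — a calibration to the expected
direction pattern, not a claim about physiology. One RNG substream per
participant and stage derives from the master seed, so participant
*i*'s data are bit-stable when the cohort grows.

What a green test establishes, and what it does not: the generator
emulates marginal distributions, the shift calendar and a linear
outcome model with independent behaviours. Real accelerometer data have
within-day autocorrelation, behaviour–behaviour and
behaviour–covariate correlation, non-Gaussian outcomes and wear
artefacts; recovery and coverage results here certify the estimator and
the plumbing, not robustness to those features.

## Numerical and design choices

* Day windows tolerate 1 s of floating-point slack when cutting 24-h
  segments (POSIXct doubles cannot represent sub-second offsets at
  epoch-time magnitudes); the partition invariant is asserted to 1/60
  min.
* A "valid day" requires ≥ 1380 covered minutes (1 h tolerance) and no
  partial flag; both thresholds are arguments.
* Rounding day minutes to the 1-min epoch grid can overflow the budget
  by ≤ 2 min; the overflow is taken out of SB, and the ground truth
  records the adjusted values, keeping the round trip exact.
* The Wilcoxon day-type comparison uses the normal approximation with
  continuity correction (n = 66 is beyond exact-table territory); an
  all-zero difference vector reports `p = NA` with a note.
* Self-substitution is an error by definition, not an estimate of 0.
* The cascade validates contradictions (wear data present but
  `wore_device = FALSE`) instead of silently trusting flags.

## Known limitations

Alcohol is a single binary covariate, identical across day types.
No compositional (log-ratio) modelling, mixed effects, imputation or
causal estimators — the models here are deliberately the plain OLS
formulations they reproduce. Per-cell significance without multiplicity
control inflates the family-wise error over the 11 × 2 grid; the
direction-pattern test therefore also monitors the pooled
false-positive rate of null cells rather than expecting them all to be
quiet at once.
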