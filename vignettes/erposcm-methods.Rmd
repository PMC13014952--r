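---
title: "Synthetic-control evaluation of ERPO laws: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic-control evaluation of ERPO laws: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erposcm)
```

## The estimation problem

Extreme Risk Protection Orders (ERPOs, "red flag" laws) let courts
temporarily remove firearm access from individuals judged at risk of harming
themselves or others. Because states adopted these laws at different times,
with different provisions and very different uptake, a pooled two-way
fixed-effects design would average over genuinely heterogeneous policies.
`erposcm` instead estimates a *state-specific* effect for each adopting
state with the Abadie–Diamond–Hainmueller synthetic control method, using
state-month rates of firearm-violence incidents that caused at least one
injury or death (incidents per 1,000,000 residents per month) as the
outcome.

For a treated state, the counterfactual is a convex combination of
never-adopting "donor" states: weights $W$ ($W_j \ge 0$, $\sum_j W_j = 1$)
are chosen so that the weighted donor average matches the treated state's
pre-policy predictors. The monthly **gap** (observed minus synthetic rate)
estimates the policy effect after the effective date; pre-policy gaps
measure fit quality.

## Cohort construction

A state enters the treated cohort only if

1. its ERPO became effective on or after 2015-01-01 (enough pre-policy
   months),
2. on or before 2019-01-01 (enough post-policy months) — both bounds are
   inclusive, because a law effective exactly on 2019-01-01 still leaves
   three post-policy years in a panel ending 2021-12, and
3. petitions were actually filed after enactment: a one-sample t-test of
   post-enactment monthly petition counts against zero, one-sided
   ($\alpha = 0.05$). Pre-enactment petition volume is structurally zero
   (the order type did not exist), which is why the null is a zero mean
   rather than a paired pre/post comparison. A two-sided option is provided;
   the one-sided reading is the default because the inclusion criterion is
   an *increase* in uptake. An all-zero post-enactment series fails; a
   constant positive series passes with the p-value reported at the machine
   floor, since a t statistic is undefined at zero variance.

Donors are states with no effective date inside the panel window
(2014-01 .. 2021-12) and complete covariate data. A state whose law predates
the panel window entirely is donor-eligible under this rule only if its
covariate record is complete; states adopting in 2019–2021 are neither
treated nor donors. The packaged `erpo_policy_catalog()` encodes the ten
treated-state effective dates verbatim; dates and completeness flags for the
other forty states are approximate plumbing chosen so the catalog reproduces
the documented 10-treated / 25-donor geometry, and one of them (Colorado) is
deliberately placed inside the enrollment window so that the petition-uptake
filter — not the date filter — is what excludes it.

The panel ends at 2021-12 by default because the upstream incident source
changed how it captures self-directed violence from 2022 onward; extending
the window is possible but warns.

## Outcome construction

Incident records carry a state, date, victim counts, and an intent label.
Records with no injuries or deaths (warning shots, gun-involved robberies
without casualties) are excluded. The outcome counts **incidents, not
victims**: victim counts are retained only to classify fatality. Each
injurious incident maps to categories:

| intent | fatal? | elementary category |
|---|---|---|
| assault | yes | homicide |
| assault | no | nonfatal_assault |
| self_harm | yes | suicide |
| self_harm | no | nonfatal_self_harm |
| unintentional / undetermined | — | (all_violence only) |

`other_directed` = nonfatal_assault + homicide, `self_directed` =
nonfatal_self_harm + suicide, and `all_violence` contains everything. An
incident with both a death and a nonfatal injury of the same intent counts
in the fatal category only; this *fatal dominance* rule keeps the elementary
categories additive within each composite. Mixed-intent multi-victim
incidents are not emitted by the simulator and, if present in real data,
are classified by the single intent label on the record.

Population denominators are annual (each calendar month uses its year's
resident count); no sub-annual interpolation is attempted because monthly
population estimates would add noise without changing any conclusion at
this scale.

## The fit: inner and outer problems

Given treated predictors $X_1$ (a $k$-vector), donor predictors $X_0$
($k \times J$), and importance weights $V$ on the predictors, the inner
problem is the simplex-constrained quadratic program

$$ W(V) = \arg\min_{W \in \Delta^{J-1}} (X_1 - X_0 W)^\top \mathrm{diag}(V) (X_1 - X_0 W). $$

`solve_simplex_qp()` solves it exactly with a primal active-set method:
equality-constrained KKT solves on the free set, partial steps when a bound
blocks, and multiplier checks on the active bounds. The Gram matrix is
usually rank-deficient ($k < J$), so a ridge of order $10^{-11}$ times its
mean diagonal makes the minimizer unique; among equally optimal vertices
this resolves deterministically toward the minimum-norm solution. The
returned weights satisfy the simplex constraints to $10^{-8}$ on every
input, and on all small instances the attained objective matches an
exhaustive simplex grid search (step 0.005) to $10^{-4}$.

Predictors are z-scored across units (treated + donors) before $V$ is
applied, so importance weights act on comparable scales; a predictor with
zero cross-unit variance cannot be standardized and is dropped with a
warning. Covariates observed at state-year resolution are repeated across
that year's months before pre-period aggregation (`mean` or `last`).
Outcome lags default to the means of the first, middle, and last thirds of
the pre-period (`lags = "thirds"`), anchoring level and shape without using
every month; `lags = "all"` uses each pre-period month as its own predictor,
which makes the equal-importance inner solve minimize the pre-period MSPE
directly and is the configuration used for the heavier simulation checks.

The outer problem chooses $V$ to minimize the pre-period outcome MSPE
$\|Z_1 - Z_0 W(V)\|^2 / T_0$ (the *nested* variant, the default). The search
runs over a softmax parameterization of the simplex with Nelder–Mead from an
equal-importance start plus seeded random restarts (default 10, relative
tolerance $10^{-8}$); because the equal-$V$ evaluation is always kept as an
incumbent, the optimized fit is never worse than the equal-importance
baseline, and results are bitwise reproducible given the seed. A fixed
equal-importance mode (`v_method = "equal"`) is also provided; whether the
original analyses used the nested optimizer is not documented, so both are
available and the choice is recorded in the fit object.

The calendar month containing the effective date is the **first post-policy
month** (e.g., an effective date of 2016-12-08 makes 2016-12 post). The
effective month is partially treated either way; assigning it to the post
period means no treated month ever leaks into the fitting period.

## Inference

For each treated state the in-space placebo ensemble refits every donor as
pseudo-treated against the remaining donors (the true treated unit never
enters a placebo's pool), with the same treatment month and predictor spec.
The test statistic is the post/pre RMSPE ratio; the permutation p-value is
`rank / n_units` where the rank counts units with strictly larger ratios
plus one (ties count against the treated unit). The denominator includes
the treated unit: with 25 donors the smallest attainable p-value is
$1/26 \approx 0.04$. Extremity is one-sided in the ratio: gaps are signed,
but the ratio measures divergence in either direction. No placebo is
dropped for poor pre-fit by default — the ratio statistic self-normalizes —
but a conventional filter (drop placebos whose pre-RMSPE exceeds a multiple
of the treated unit's) is available as `filter_ratio`.

**Fit gate.** An estimate is reported only when the pre-policy fit is good:
pre-period RMSPE at most `tau1 = 0.10` of the unit's own pre-period mean
rate, and at most `tau2 = 2` times the median placebo pre-RMSPE. Small
states fail the first test easily — with monthly counts around $c$, pure
count noise alone puts the relative RMSPE near $1/\sqrt{c}$ — which is
exactly the intended behavior: volatile small-state panels produce
uninterpretable fits.

**Yearly effects.** Implementation years are consecutive 12-month blocks
from the treatment month. The effect for a year is the **sum of that
year's monthly gaps** (incidents per 1,000,000 residents per year);
percent change divides by the synthetic control's annual rate over the same
block. The annual-sum scale was chosen because a monthly-scale reading of
headline effects would imply implausibly small baselines, while the
annual-sum reading is consistent with a baseline of roughly 60 incidents
per 1M per year. Interval construction for such effects is not standardized;
two clearly labeled options are provided: the default "monthly-variation"
normal interval, effect $\pm z_{0.975}\sqrt{12}\,\mathrm{sd}$(monthly gaps
in the block), and a placebo-quantile band (2.5th/97.5th percentiles of the
placebo units' yearly effects), which is a null band rather than an interval
centered on the estimate. Neither is asserted to be the construction used in
any prior analysis.

Stratified re-analyses (nonfatal assault, homicide, other-directed,
nonfatal self-harm, suicide, self-directed) are complete independent runs on
the stratum's own panel — own fit, own placebo ensemble, own p-value — not
decompositions of the all-violence estimate.

## The simulator

`generate_panel()` draws the latent monthly rate
$$ \lambda_{it} = \max\!\big(0,\; \delta_t + \textstyle\sum_r F_{rt}\,\mu_{ir} + \mathrm{covid}_t + \mathrm{effect}_{it} + \varepsilon_{it}\big), $$
with counts $\sim$ Poisson$(\lambda_{it}\,\mathrm{pop}_i/10^6)$. Defaults
emulate the study conditions: 10 treated + 25 donor units, 96 months
(2014-01..2021-12), effective dates spread evenly over 2016-01..2019-01,
two AR(1)-smoothed latent factors carrying half the baseline, a seasonal
common trend, a +20% common level shock from 2020-03 (the pandemic period),
a baseline of 60 incidents per 1M per year, Gaussian rate noise of 0.3 per
1M per month, and log-uniform state populations between 0.6M and 8M.
Poisson counts — rather than Gaussian rates — are what make small simulated
states volatile, mirroring why small-state panels gate out.

Treated loadings are drawn inside the donor convex hull (`overlap = TRUE`),
so a good synthetic control exists, or outside it (`overlap = FALSE`) to
exercise the fit gate. Covariates are noisy linear functions of the latent
loadings, so they genuinely inform the fit. Petition series are zero before
the effective date and Poisson after, with optional year-on-year growth.
`generate_incidents()` disaggregates each cell's count into records via
multinomial intent draws (default 70% assault / 20% self-harm / 10%
unintentional) and Bernoulli fatality (25% / 85% / 5%), chosen as
plausible magnitudes for media-sourced incident data in which fatal
self-harm dominates captured self-directed events; aggregating the records
reproduces the panel cell-for-cell.

Two things the simulator deliberately does not model: spatial correlation
between neighboring states and within-state (county-level) heterogeneity.
Passing tests therefore demonstrate the pipeline's statistical behavior
under a linear factor model with independent count noise — not that real
incident data satisfies those assumptions.

**Weight identifiability.** Under a low-rank factor model, many convex
donor combinations reproduce the same loadings, so the weight vector itself
is not identified when there are more donors than factors; the synthetic
*series* and the gaps are. Tests that assert exact weight recovery
therefore use geometries where the weights are unique (two donors, or a
duplicated donor under count noise); recovery tests otherwise target the
gaps and effects.

## Numerical and scale choices

- Inner QP: ridge $\approx 10^{-11}\,\overline{\mathrm{diag}(H)}$;
  feasibility tolerance $10^{-10}$; simplex sum restored exactly by
  renormalization after clipping.
- Outer search: 10 seeded starts by default; simulation-heavy checks use
  `v_method = "equal"` with `lags = "all"`, which needs no outer search.
- Calibration checks designate a unit drawn from the *donor* loading
  distribution as treated: hull-interior treated units are systematically
  easier to fit than uniformly drawn donors, so they are not exchangeable
  with the placebo ensemble and would miscalibrate any permutation test.
- Problem sizes in the test suite: 500 null panels (26 units × 96 months)
  for type-I calibration; 200 replicates for step-effect recovery and 100
  for ramp monotonicity; 100 random instances against the simplex grid
  oracle. These sizes keep Monte-Carlo error well below the margins being
  asserted.
- The petition t-test, ranking p-value, and all cohort logic are exact and
  deterministic; every stochastic routine takes an integer seed and is
  bitwise reproducible from it.

## Known limitations

- The placebo p-value has granularity $1/n$; with 25 donors, "significant at
  0.05" means exactly rank 1.
- The fit gate's `tau1` compares RMSPE to the unit's own mean rate; for
  very low-rate strata (e.g., suicide counts in small states) the
  placebo-relative `tau2` test carries the weight, and a zero pre-period
  mean rate disables `tau1` entirely.
- Donor-order invariance of ratios holds to solver tolerance
  ($\sim 10^{-7}$ relative), not bitwise, on degenerate fits.
- Covariate support requires complete unit-year coverage over the
  pre-period; missing cells are an error rather than an imputation.
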