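---
title: "Methods: trial-based economic evaluation of a three-arm lifestyle intervention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based economic evaluation of a three-arm lifestyle intervention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifecea)
```

## The evaluation problem

`lifecea` evaluates, from a societal perspective, whether web-based
tailored lifestyle advice is worth its costs relative to a minimal
intervention, using two effect measures observed alongside a 24-month
randomized trial with three arms (sequential advice, simultaneous advice,
control):

* **cost-effectiveness**: cost per additional public-health guideline met
  (the lifestyle factor score, LFS, 0–5);
* **cost-utility**: cost per quality-adjusted life year (QALY) from
  EQ-5D-3L measurements every 3 months.

Because individual-level trial data of this kind are rarely shareable, the
package pairs the analysis pipeline with a synthetic-trial generator that
reproduces the statistical structure the analysis assumes. Everything
downstream of the generator treats its output exactly as it would treat
real long-format questionnaire exports.

## Effects

### Guideline adherence and the LFS

Adherence is evaluated on the behaviours' natural scales against five
guidelines: moderate physical activity ≥30 min on at least 5 days/week,
≥2 pieces of fruit/day, ≥200 g vegetables/day, at most 1 (women) or
2 (men) glasses of alcohol/day, and non-smoking. Boundary values adhere
("at least" / "not more than"), which the tests pin down explicitly. The
LFS sums the five indicators; a missing behaviour makes the score missing
rather than silently counting as non-adherence. The LFCI is the 24-month
minus the baseline score (−5..+5).

The 24-month LFS is discounted by dividing the score by 1 + r_effect
(default 1.5%), because it is measured in the second study year. A
discounted adherence count is admittedly unusual; the raw score is kept
alongside, and the change-from-baseline scenario uses the raw LFCI since
a discounted difference of counts has no clean interpretation.

### EQ-5D-3L utilities and QALYs

Utilities use the published Dutch value set in the standard additive form
(constant term for any impairment, per-dimension level decrements, N3 term
for any level-3 response), embedded as data and pluggable through a CSV
registry so other EQ-5D-3L tariffs can be substituted. Under this tariff
the worst state 33333 scores −0.329 and full health 11111 scores exactly
1; the package validates every input level and refuses silent recoding.
One caveat is deliberate: the tariff anchors *death* at 0 and merely
reaches −0.329 for the worst living state, although the range is sometimes
loosely described as "−0.33 (death) to 1". The implementation follows the
published value set.

QALYs integrate the nine-point utility trajectory (months 0, 3, …, 24) by
the area-under-the-curve method. Both the trapezoid rule (default) and the
rectangle (carry-forward) rule are available via `auc_method`; they
coincide for constant trajectories, and the trapezoid is the conventional
choice when utilities move. Segments lying in the second year are
discounted by 1/(1 + r_effect); the month-12 point anchors year 1, so the
segment spanning months 12–15 is the first discounted one. For a constant
utility *u* this gives u·(1 + 1/1.015) discounted QALYs, which the tests
use as a closed form.

## Costs

All valuation parameters are configuration, not code: unit prices per
resource category each carry their own price year; hourly wage costs come
from a gender × age-band table (half-open bands); travel uses an average
distance per visit and a price per km; per-arm intervention time defaults
to 70/100/20 minutes (sequential/simultaneous/control) and hosting to
€0.54 per participant. The shipped `default_unit_costs()` is a
round-number fixture (€10/item medication, €30/visit, €250/admission-day,
€25/hour other care, €36/hour wage): with it the control arm's 20 minutes
of website time values to exactly €12, and simulated biennial totals land
in the realistic €3,500–€5,000 band. Real analyses substitute the
applicable costing-manual prices via `read_unit_costs()`.

Prices are indexed to the 2013 reference year with the Dutch CPI series
(105.38 in 2009 through 115.00 in 2013); indexing is the plain ratio of
index values and is transitive, which a test verifies. Productivity costs
follow the human capital method — absenteeism days (truncated to the
90-day quarter) times the wage-band day cost — and are valued only for
employed participants, a switch the evaluation exposes because reasonable
analyses differ here. Second-year amounts (quarters 5–8) are divided by
1 + r_cost (default 4%). The intervention time cost is treated as incurred
at entry and is not discounted. Totals are exactly additive over
components; a dedicated test isolates each category by zeroing the others'
prices.

## Missing data

The cascade is deliberately simple, single imputation, in a fixed order:

1. **truncation** of implausible values to their bounds (so an implausible
   observation can never be carried into a gap — permuting this order
   changes results, and a regression test holds a counterexample);
2. **per-series imputation** over quarters 0..8 for every variable:
   a single interior gap takes the mean of its neighbours; longer or
   trailing gaps take LOCF; leading gaps (missing baseline) take NOCB.
   EQ-5D items are imputed on the 1–3 level scale per dimension and then
   re-scored; a half-level rounds away from zero and is clamped to {1,2,3};
3. **study-group means** for free-text answers that cannot be valued, with
   the overall mean as a logged fallback.

One ambiguity is resolved and documented rather than hidden: an interior
gap longer than one point could arguably be re-bridged by neighbour means;
the literal cascade (LOCF from the left edge) is used. Participants whose
entire series for a variable is missing stay missing and drop listwise
from statistics that need that variable — which is why cost, LFS and QALY
analysis sets can have different sizes. Inclusion requires a computable
baseline LFS and a completed baseline economic questionnaire.
Completeness for the ≥50%-follow-ups scenario is counted on the
questionnaires actually returned, before any imputation.

## Incremental analysis and uncertainty

ICERs are ΔC/ΔE with full-precision internals and 2-decimal half-up
rounding for reporting. Dominance is classified before any division:
higher cost with lower effect is *dominated*, the mirror is *dominant*,
and equal effects with unequal costs yield an explicit "icer undefined"
rather than an infinity. The bootstrap resamples participants with
replacement *within each arm* (the trial's randomized sizes are part of
the design, so stratification is the appropriate resampling scheme), and
acceptability curves award each replicate's win to the arm with the
highest replicate-mean net monetary benefit, splitting ties equally so
probabilities sum to one exactly. The willingness-to-pay grid spans
€0–€80,000 with €18,000 as the conventional reporting threshold.

## Sensitivity scenarios

The primary analysis and the seven sensitivity analyses are declarative
`scenario()` objects over the same prepared data, which keeps imputation
out of the re-analysis loop: prepared data retain undiscounted quarterly
component costs and full utility trajectories, and each scenario
re-aggregates with its own perspective, discount rates and effect variant.
The scenarios: (1) health care perspective (productivity and respondent
costs excluded — enforced, not merely conventional); (2) productivity
costs excluded; (3) at least 4 of 8 follow-ups; (4) change-from-baseline
outcomes; (5) exclusion above the 95th percentile of total costs, one
global threshold computed once on the pre-exclusion population (a single
pass — re-applying the rule iteratively would keep shaving the tail);
(6) no discounting; (7) 4% on both costs and effects.

For the baseline-corrected QALY (scenario 4) the adjustment formula is a
genuine open choice. The default removes the pooled linear association
with baseline utility (`QALY − b·(u₀ − ū₀)`, b from a pooled regression,
the conventional covariate adjustment); a baseline-anchored variant
(`QALY − u₀·D(r)`, D the discounted duration) is exposed through
`qaly_adjust_method` for analysts who prefer a model-free contrast.

## The synthetic-trial generator

Defaults encode the reference study conditions: arms of 552/517/664;
ages uniform on 18–65; 47% female; 70% employed; baseline utilities from
per-dimension ordinal probabilities tuned so the Dutch-tariff mean is
≈0.89 (SD ≈0.13, the documented ceiling effect); baseline adherence
probabilities (0.55/0.55/0.55/0.85/0.80) summing to a mean LFS of 3.3;
quarterly resource counts from gamma-Poisson (negative binomial) mixtures,
hence nonnegative and right-skewed; absenteeism rates of 2.2/2.2/1.6
days/quarter reflecting the observed baseline imbalance; and 24-month
arm effects of +0.10/+0.15/+0.05 guidelines and −0.01/−0.03/0 QALYs —
small by design, as in the trial.

Missingness is a two-component missing-at-random mechanism, the simplest
structure matching the reported phenomena: a logistic model on centred age
and baseline LFS (intercept logit(0.292), slopes −0.02 and −0.12) decides
whether a participant returns *no* follow-up economic questionnaire
(≈29% — younger and less healthy participants more often); survivors then
face a per-quarter attrition hazard of 0.08 from quarter 2 onward
(monotone: once gone, gone), chosen so per-questionnaire completion decays
through the high-30s-to-high-60s percent range over the eight quarters;
returned questionnaires additionally lose each item independently with
probability 0.03. Centring the covariates makes the intercept directly
interpretable as the marginal dropout logit. Baseline is complete by
construction: the configured arm sizes are the sizes of the *included*
analysis set.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: within-person correlation of resource
use over time (counts are drawn independently per quarter), correlation
between cost categories, informative missingness beyond the age/LFS
mechanism, seasonal patterns, and the raw behaviour instruments (the
generator emits behaviour summaries, not questionnaire items). 24-month
adherence is drawn independently of baseline adherence given the arm
shift, which makes configured effects exactly recoverable in expectation
but understates within-person behavioural tracking, so LFCI variances run
higher than a real cohort's.

## Numerical and testing choices

Determinism: every stochastic entry point takes a seed; the same seed and
configuration produce byte-identical datasets, bootstrap draws and
scenario tables. The test suite exercises the tariff against an
independent re-statement of the additive model over all 243 states;
closed-form discounting identities (1 + 1/1.015 QALYs, 400 + 400/1.04
flat-cost totals, the 115.00/105.38 CPI ratio); and pipeline parameter
recovery — with a configured €200 cost and 0.05-guideline effect at
600 participants/arm, the bootstrap 95% interval of the ICER covers the
generating €4,000 per guideline in at least 18 of 20 seeded repetitions.
These simulation sizes (up to 2,000 participants/arm for null-effect
equivalence, 600/arm × 20 repetitions for recovery, 1,000 bootstrap
replicates) were chosen as the smallest giving stable Monte-Carlo margins
for the properties tested.

Known limitations: single imputation understates uncertainty relative to
multiple imputation (a deliberate scope choice); the ICER bootstrap
distribution is heavy-tailed when effect differences are near zero, so
percentile intervals for ICERs should be read alongside the acceptability
curves, which remain well-behaved; and presenteeism is not modelled
anywhere in the costing.
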