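---
title: "Methods: trial- and model-based cost-utility analysis of early cognitive therapy for child PTSD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial- and model-based cost-utility analysis of early cognitive therapy for child PTSD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptsdcea)
```

## The evaluation problem

`ptsdcea` implements an economic evaluation of early trauma-focused
cognitive therapy (CT-PTSD) for children and adolescents with
post-traumatic stress disorder, compared with waitlist usual care, from a
UK NHS/PSS perspective. The evaluation has two horizons:

1. **Trial horizon** (11 weeks): per-patient costs from service-use
   questionnaires priced with unit costs, plus the intervention cost from
   therapist contact time; QALYs from SDQ-mapped utilities; missing
   follow-up data imputed by conditional regression; covariate-adjusted
   incremental costs and QALYs; the ICER.
2. **Model horizon** (3 years): a two-state Markov cohort model (PTSD /
   PTSD-free) extrapolating beyond the trial, with probabilistic and
   one-way sensitivity analysis.

## Utility mapping and QALYs

Utilities come from a published linear crosswalk from the five
parent-rated SDQ subscales (each scored 0–10) to the CHU-9D child utility
index:

$$U = 0.88 - 0.019\,\text{emotion} - 0.009\,\text{conduct}
      - 0.001\,\text{hyper} - 0.008\,\text{peer}
      + 0.005\,\text{prosocial}$$

On the valid domain the mapping spans exactly [0.51, 0.93], so no
clamping is applied; out-of-domain scores are rejected with an error
naming the offending subscale. QALYs between two assessments are the
trapezoid `duration × (u_start + u_end) / 2`. The trial window is
11/52.18 years; utilities within the window are not discounted (the
horizon is under a year). These choices give trial QALYs of the observed
~0.18–0.20 magnitude.

## Costing

Service-use counts are priced category by category against a unit-cost
table (GBP, 2014 price year). The table packaged in
`inst/extdata/unit_costs.csv` is a *synthetic, illustrative* fixture with
magnitudes loosely modelled on published UK child mental-health unit
costs; the trial's own per-category unit costs were never published, so
exact reproduction of the trial's cost table is not attempted. Categories
attributable to the index trauma itself (emergency department,
ambulance) carry a flag and are excluded by default. The intervention is
costed as contact minutes × £138/hour (clinical psychologist, including
on-costs and overheads); arithmetic is kept unrounded and only reports
round to the pound, so 636.25 minutes prices at £1463.375 and reports as
£1463.

## Trial-horizon analysis

- **Imputation.** "Conditional regression" is implemented as single
  deterministic regression imputation: missing follow-up costs and
  utilities are replaced by predictions from a linear model on arm, the
  corresponding baseline value, age and gender. With 29 participants,
  multiple imputation would be over-engineered; seeded residual noise is
  available behind an argument for users who want stochastic imputation.
- **Adjustment.** The "generalized linear model" is an identity-link
  Gaussian model by default, so the group coefficient is directly a
  difference in GBP or QALYs; a Gamma log-link option (group effect as a
  difference of adjusted response-scale predictions) is provided for
  heavily skewed costs.
- **ICER.** `compute_icer()` divides unrounded differences and records
  the cost-effectiveness-plane quadrant; pure dominance (cheaper and more
  effective, or the reverse) is labelled rather than reported as a
  ratio, and a zero QALY difference raises a classed warning directing
  users to net monetary benefit.

## The two-state cohort model

Children enter at the end of the trial, split PTSD-free/PTSD by their
arm's recovery proportion (defaults 0.71 treated, 0.27 usual care).
Twelve 3-month cycles cover 3 years; cycle 1 carries the arm's observed
trial cost and QALYs (imputed analysis values: £1,686/0.1979 treated,
£307/0.1823 control), accepting the 11-week-vs-13-week approximation.
Natural recovery applies in cycles 2–4 only, to both arms' residual PTSD
mass, with per-cycle probability 0.129 obtained from a 9-month
meta-analytic estimate of 0.34 by rate conversion
(`1 − exp(log(1 − p) · t_short/t_long)`). PTSD-free is absorbing: no
relapse, and no recovery in years 2–3. State values per cycle are £549 /
0.185 (PTSD) and £236 / 0.193 (PTSD-free).

Conventions that were genuinely open, and how they were fixed:

- **Transition timing.** Recovery is applied at the *start* of each
  modelled cycle, before accrual. With the 3-month state values this
  reproduces the published year-1 cumulative totals (control
  £1,540/0.748, treatment £2,598) to within 0.5%; end-of-cycle timing
  does not.
- **State values.** The published annual state values (£2,596/£1,114)
  are mutually inconsistent with the 3-month values (£549 × 4 = £2,196 ≠
  £2,596). The 3-month values are canonical here because they reproduce
  the year-1 totals; the annual table is informational only.
- **Discounting.** Year 1 is undiscounted; cycles in year *y* ≥ 2 share
  the factor 1/(1.035)^(y−1). A per-cycle variant (discounting by time
  elapsed past year 1) is available but non-default.
- **Half-cycle correction.** None is applied by default — the year-1
  reproduction succeeds without it — but it exists behind
  `half_cycle_correction = TRUE`.
- **Year 2–3 totals.** The published year-2/3 cumulative totals and
  3-year ICER (printed inconsistently as £2,205 and £2,250) could not be
  reproduced under any combination of timing and discounting conventions
  tried, and are treated as non-canonical. The engine is instead
  validated by structure: occupancy conservation to 1e−12, absorbing-state
  monotonicity, a zero-rate discounting identity, and agreement with an
  independent patient-level microsimulation at 10^5 individuals.

## Probabilistic sensitivity analysis

Each of 5,000 draws samples, independently (no correlation structure is
published): arm efficacies Beta(19, 7) and Beta(3, 9); state costs
Gamma(19.532, scale 28.118) and Gamma(10.369, scale 22.738), whose means
recover £549 and £236; per-cycle state QALYs from Betas; and the natural
recovery probability. Trial-cycle costs and QALYs are held fixed — no
uncertainty distribution is published for them. Both arms' 3-year cohorts
are re-run per draw and incremental costs and QALYs recorded at each year
boundary; the CEAC is the fraction of draws with positive net monetary
benefit λ·ΔE − ΔC over a £0–£50,000 grid in £500 steps (covering the
£20,000–£30,000 decision anchors).

Two published ambiguities are resolved explicitly:

- The two state-QALY Betas are printed against the wrong states
  (Beta(2618, 10940) has mean 0.193 but is listed for the 0.185 state,
  and vice versa). Each Beta is assigned to the state whose stated mean
  it matches, and `psa_distributions()` warns about the swap.
- The remission row lists a 9-month summary, 34% (21%–49%), next to a
  Beta(14, 95) whose mean (0.128) is on the 3-month scale. By default the
  9-month proportion is sampled from a Beta fitted numerically to the
  stated mean and 95% CI (≈ Beta(14.5, 28.0)) and converted per draw;
  `remission_scale = "three_month"` uses the printed pair directly.

One-way variants re-run everything under stated overrides only: the
training-cost variant adds the straight-line amortized £186 per treated
patient (total / (5 years × 29 patients/year)) to the treatment arm's
cycle-1 cost; the complete-case variant sets initial PTSD-free
proportions to 0.90/0.18 and PTSD-free cycle values to £264.55/0.2027.
The published training-cost ICER (£16,187) is not derivable from the
printed increments plus £186 and is checked only via additivity: the
variant's ΔC exceeds the base ΔC by exactly the amortized amount.

## The synthetic cohort generator

No patient-level data are deposited, so `generate_cohort()` draws
datasets with the structure the analysis assumes: arms of 14/15, everyone
PTSD-positive at entry, follow-up recovery Bernoulli(0.71)/Bernoulli(0.27),
SDQ subscales as bounded binomial integers whose mapped utilities average
≈0.734 with PTSD and ≈0.925 when recovered, zero-inflated geometric
resource-use counts (matching the zero-heavy, right-skewed published cost
pattern), contact minutes from a Beta scaled to [195, 755] with mean
636.25 (concentration 7 — a judgement call giving a realistic left-skewed
contact-time spread), ages uniform on 8–17 and gender Bernoulli(0.5)
purely to exercise the adjustment model, and 20% follow-up-block
missingness, completely at random per record (the published missingness
test, p = .366, does not support an arm-dependent mechanism). Costs and
outcomes are independent given recovery status by default; a correlation
knob exists because the real within-arm correlation structure is
unpublished — its default is a guess of independence, stated as such.

What passing tests on synthetic cohorts show — and do not show: they
verify the pipeline's arithmetic, invariants and estimator consistency
(configured recovery proportions are recovered within Monte-Carlo error
at 5,000 per arm), but they cannot validate the clinical realism of the
published parameter estimates themselves, nor reproduce the exact trial
tables, whose underlying unit costs and raw data are unavailable.

## Problem sizes and numerical notes

The test suite uses cohorts of 29 (trial scale) for end-to-end runs,
5,000–10,000 for sampling-oracle checks, 10^5 individuals for the
microsimulation cross-check, and 5,000 PSA draws (the published number);
the full suite runs in seconds. The Beta-from-CI fit minimises squared
quantile error with a moment-matched start; imputation and adjustment
reject singular designs and all-missing predictors with classed errors;
ICERs are computed on unrounded values and rounded only for display.

## Known limitations

- The packaged unit-cost table is illustrative; per-category published
  costs do not exist, so absolute cost levels from synthetic cohorts are
  not comparable to the published cost table.
- Year-2/3 published totals are not reproducible from the printed inputs
  (see above); only year-1 totals are treated as checkable.
- PSA parameters are sampled independently; any true correlation between
  efficacy and state values is ignored.
- The generator's utility separation between recovered and non-recovered
  children is a configured target, not an estimate from patient data.
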