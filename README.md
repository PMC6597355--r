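# ptsdcea

Trial- and model-based **cost-utility analysis of early trauma-focused
cognitive therapy (CT-PTSD)** for children and adolescents with
post-traumatic stress disorder, compared with waitlist usual care, from a
UK NHS/PSS perspective.

The package is for health economists and methodologists who want the full
evaluation pipeline as tested, reusable code rather than a spreadsheet:

- **Synthetic trial cohorts** — seeded patient-level datasets with the
  trial's structure (arms of 14/15, recovery proportions 0.71/0.27,
  SDQ-based utilities, zero-heavy right-skewed service use, ~20%
  follow-up missingness), so every stage is testable without real data.
- **Utilities and QALYs** — the published linear SDQ→CHU-9D crosswalk
  `U = 0.88 − 0.019·emotion − 0.009·conduct − 0.001·hyper − 0.008·peer +
  0.005·prosocial` and trapezoidal QALY accrual.
- **Costing** — unit-cost pricing of service use (with index-trauma
  exclusion) and intervention costing at £138/hour of therapist contact.
- **Trial incremental analysis** — conditional-regression imputation,
  covariate-adjusted (group, baseline, age, gender) cost and QALY
  differences, and the ICER ΔC/ΔE with dominance classification.
- **Two-state Markov extrapolation** — PTSD / PTSD-free cohort model over
  twelve 3-month cycles (3 years), natural recovery at 0.129 per cycle in
  year 1 only (rate-converted from a 9-month probability of 0.34), an
  absorbing PTSD-free state, and 3.5% annual discounting after year 1.
- **Uncertainty** — 5,000-draw probabilistic sensitivity analysis over
  published Beta/Gamma parameter distributions, cost-effectiveness plane
  and acceptability curves (CEAC = P(λ·ΔE − ΔC > 0)), and one-way
  variants (amortized therapist-training costs, complete-case analysis).

Everything is tibble-in/tibble-out and pipe-friendly, with
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

```r
library(ptsdcea)

# 1. a seeded synthetic trial cohort (14 treated, 15 usual care)
rec <- generate_cohort(cohort_config(seed = 2024))

# 2. trial-horizon cost-utility analysis with imputation and adjustment
trial_cua(rec, seed = 2024)
#> Trial cost-utility analysis (imputed data)
#> # A tibble: 2 × 6
#>   arm           n mean_cost sd_cost mean_qaly sd_qaly
#>   <fct>     <int>     <dbl>   <dbl>     <dbl>   <dbl>
#> 1 treatment    14     1793.    151.     0.168 0.0119
#> 2 control      15      430.    344.     0.163 0.00972
#>
#> Adjusted incremental cost: 1395 GBP; incremental QALYs: 0.00449
#> ICER: 310368 GBP/QALY (quadrant NE)
```

The treated arm's costs are dominated by the intervention itself (~£1,463
for a mean 636.25 contact minutes); over only 11 weeks the QALY gain is
tiny, so the trial-horizon ICER is far above any decision threshold —
which is why the model extrapolation matters.

```r
# 3. three-year Markov extrapolation (published parameter defaults)
markov_cua()$by_year
#> # A tibble: 3 × 8
#>    year cost_treatment cost_control cost_diff qaly_treatment qaly_control
#>   <dbl>          <dbl>        <dbl>     <dbl>          <dbl>        <dbl>
#> 1     1          2602.        1538.     1064.          0.772        0.748
#> 2     2          3746.        3034.      712.          1.51         1.48
#> 3     3          4851.        4479.      372.          2.23         2.19

# 4. probabilistic sensitivity analysis and acceptability
draws <- sample_psa(5000, seed = 2024)
glance(draws)
#> # A tibble: 1 × 7
#>   n_draws mean_delta_cost mean_delta_qaly frac_ne frac_dominant frac_dominated
#>     <int>           <dbl>           <dbl>   <dbl>         <dbl>          <dbl>
#> 1    5000            266.          0.0450   0.682         0.293         0.0158

cv <- ceac(draws)
cv[cv$threshold %in% c(20000, 30000), ]
#> # A tibble: 2 × 2
#>   threshold probability
#>       <dbl>       <dbl>
#> 1     20000       0.732
#> 2     30000       0.834

plot_ce_plane(draws, wtp = 20000)   # cost-effectiveness plane
autoplot(cv)                        # acceptability curve
```

As the upfront therapy cost is offset by lower service use and better
quality of life among the (mostly treated) recovered children, the
incremental cost shrinks year on year while the QALY gain grows; about
68% of PSA draws land in the north-east quadrant at 3 years, and
treatment is cost-effective in roughly 73–83% of draws at the
£20,000–£30,000/QALY thresholds.

See `vignettes/cost-utility-methods.Rmd` for the model conventions,
distribution choices and known limitations.

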