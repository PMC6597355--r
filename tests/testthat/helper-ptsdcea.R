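# Minimal hand-built patient records for costing and trial-analysis tests:
# two resource categories (one hospital/index-trauma, one community), both
# assessment periods, explicit contact minutes.
tiny_records <- function() {
  tibble::tibble(
    id = c("A", "B", "C"),
    arm = factor(c("treatment", "treatment", "control"),
                 levels = c("treatment", "control")),
    age = c(10L, 12L, 14L),
    gender = factor(c("female", "male", "female"),
                    levels = c("female", "male")),
    ptsd_baseline = TRUE,
    ptsd_followup = c(FALSE, TRUE, TRUE),
    res_emergency_dept_baseline = c(1L, 0L, 0L),
    res_gp_surgery_baseline = c(0L, 1L, 3L),
    res_emergency_dept_followup = c(0L, 0L, 1L),
    res_gp_surgery_followup = c(2L, 0L, 1L),
    contact_minutes = c(600, 300, 0),
    followup_missing = FALSE
  )
}

tiny_unit_costs <- function() {
  structure(
    tibble::tibble(
      category = c("emergency_dept", "gp_surgery"),
      setting = c("hospital", "community"),
      unit = c("attendance", "visit"),
      cost_gbp = c(124, 45),
      index_trauma = c(TRUE, FALSE)),
    price_year = 2014,
    class = c("unit_cost_table", class(tibble::tibble())))
}

# Analysis table where the follow-up outcomes are exact linear functions of
# the predictors, so regression predictions are known in closed form.
exact_linear_table <- function() {
  tbl <- tibble::tibble(
    id = sprintf("P%d", 1:8),
    arm = factor(rep(c("treatment", "control"), each = 4),
                 levels = c("treatment", "control")),
    age = c(9, 11, 13, 15, 10, 12, 14, 16),
    gender = factor(rep(c("female", "male"), 4),
                    levels = c("female", "male")),
    followup_missing = FALSE,
    cost_baseline = c(120, 200, 310, 400, 150, 265, 350, 455),
    utility_baseline = c(0.70, 0.74, 0.72, 0.76, 0.73, 0.71, 0.77, 0.75)
  )
  tbl$cost_followup <- 50 + 80 * (tbl$arm == "treatment") +
    2 * tbl$cost_baseline + 3 * tbl$age + 20 * (tbl$gender == "male")
  tbl$utility_followup <- 0.1 + 0.05 * (tbl$arm == "treatment") +
    0.8 * tbl$utility_baseline + 0.001 * tbl$age +
    0.01 * (tbl$gender == "male")
  tbl$qaly <- accrue_qalys(tbl$utility_baseline, tbl$utility_followup,
                           trial_window_years())
  tbl
}
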