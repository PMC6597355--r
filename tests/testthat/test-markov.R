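test_that("probability conversion follows the constant-rate identity", {
  expect_equal(round(convert_probability(0.34, 9, 3), 3), 0.129)
  expect_equal(convert_probability(0, 9, 3), 0)
  expect_equal(convert_probability(0.42, 7, 7), 0.42) # identity round-trip
  # converting back recovers the input to machine precision
  p3 <- convert_probability(0.34, 9, 3)
  expect_equal(convert_probability(p3, 3, 9), 0.34, tolerance = 1e-12)
  expect_error(convert_probability(1, 9, 3), class = "ptsdcea_domain_error")
  expect_error(convert_probability(0.3, 0, 3),
               class = "ptsdcea_domain_error")
})

test_that("discounting starts after year 1 at 3.5% a year", {
  expect_equal(discount_factor(1:4), rep(1, 4))           # year 1
  expect_equal(discount_factor(5), 1 / 1.035)             # year 2
  expect_equal(discount_factor(9), 1 / 1.035^2)           # year 3
  expect_equal(discount_factor(1:12, rate = 0), rep(1, 12))
  # per-cycle mode discounts by elapsed time past year 1
  expect_equal(discount_factor(5, mode = "per_cycle"), 1.035^-0.25)
  expect_error(discount_factor(1, rate = -0.1),
               class = "ptsdcea_domain_error")
})

test_that("with no recovery and equal state values the model is closed form", {
  spec <- markov_spec(recovery_prob = 0, discount_rate = 0.035)
  vals <- state_values(cost_ptsd = 400, cost_free = 400,
                       qaly_ptsd = 0.19, qaly_free = 0.19)
  traj <- run_cohort_model(spec, vals, "control")
  disc <- discount_factor(2:12)
  expect_equal(traj$cum_cost[12], 307 + 400 * sum(disc), tolerance = 1e-12)
  expect_equal(traj$cum_qaly[12], 0.1823 + 0.19 * sum(disc),
               tolerance = 1e-12)
  # occupancies frozen at the initial split
  expect_equal(unique(traj$occupancy_free), 0.27)
})

test_that("three recovery cycles at .129 clear 1 - 0.871^3 of the PTSD mass", {
  traj <- run_cohort_model(markov_spec(), state_values(), "control")
  cleared <- 1 - traj$occupancy_ptsd[4] / traj$occupancy_ptsd[1]
  expect_equal(cleared, 1 - 0.871^3, tolerance = 1e-12)
  expect_equal(1 - 0.871^3, 0.339, tolerance = 0.001) # the 9-month 34%
})

test_that("occupancies conserve mass and PTSD-free is absorbing", {
  for (arm in c("treatment", "control")) {
    traj <- run_cohort_model(markov_spec(), state_values(), arm)
    expect_equal(traj$occupancy_ptsd + traj$occupancy_free, rep(1, 12),
                 tolerance = 1e-12)
    expect_true(all(diff(traj$occupancy_free) >= -1e-15))
    expect_true(all(diff(traj$cum_cost) >= 0))
    expect_true(all(diff(traj$cum_qaly) >= 0))
  }
})

test_that("zero discounting equals the plain cumulative sum", {
  spec0 <- markov_spec(discount_rate = 0)
  spec <- markov_spec()
  t0 <- run_cohort_model(spec0, state_values(), "treatment")
  expect_equal(t0$cum_cost[12],
               sum(t0$cost / t0$discount * 1), tolerance = 1e-12)
  expect_equal(unique(t0$discount), 1)
  # and discounted totals never exceed undiscounted ones
  t1 <- run_cohort_model(spec, state_values(), "treatment")
  expect_lt(t1$cum_cost[12], t0$cum_cost[12])
})

test_that("a patient-level microsimulation reproduces the cohort totals", {
  spec <- markov_spec()
  vals <- state_values()
  for (arm in c("treatment", "control")) {
    coh <- run_cohort_model(spec, vals, arm)
    mic <- microsimulate_arm(spec, vals, arm, n_patients = 1e5, seed = 77)
    # Monte-Carlo error of the mean at 1e5 patients: ~3 SE bounds
    expect_lt(abs(mic$cum_cost - coh$cum_cost[12]), 15)
    expect_lt(abs(mic$cum_qaly - coh$cum_qaly[12]), 0.001)
  }
})

test_that("the year-1 published totals are reproduced by the conventions", {
  tt <- run_cohort_model(markov_spec(), state_values(), "treatment")
  tc <- run_cohort_model(markov_spec(), state_values(), "control")
  y1 <- model_icer(tt, tc, year = 1)
  expect_equal(y1$arms$cost[y1$arms$arm == "control"], 1540,
               tolerance = 0.005)
  expect_equal(y1$arms$qaly[y1$arms$arm == "control"], 0.748,
               tolerance = 0.005)
  expect_equal(y1$arms$cost[y1$arms$arm == "treatment"], 2598,
               tolerance = 0.005)
  expect_equal(y1$icer$cost_diff, 1058, tolerance = 0.01)
  expect_gt(y1$icer$qaly_diff, 0)
})

test_that("model_icer degenerates correctly", {
  spec <- markov_spec()
  tt <- run_cohort_model(spec, state_values(), "treatment")
  # identical arms: zero deltas, undefined ICER
  expect_warning(same <- model_icer(tt, tt, year = 3),
                 class = "ptsdcea_undefined_icer")
  expect_equal(same$icer$cost_diff, 0)
  expect_true(is.na(same$icer$icer))
  # one cycle, no discounting: reduces to the trial ICER
  spec1 <- markov_spec(n_cycles = 1, recovery_cycles = integer(),
                       discount_rate = 0)
  t1 <- run_cohort_model(spec1, state_values(), "treatment")
  c1 <- run_cohort_model(spec1, state_values(), "control")
  trial <- model_icer(t1, c1, year = 1)
  expect_equal(trial$icer$cost_diff, 1686 - 307)
  expect_equal(trial$icer$qaly_diff, 0.1979 - 0.1823)
  expect_equal(trial$icer$icer, (1686 - 307) / (0.1979 - 0.1823))
  # mismatched horizons are rejected
  expect_error(model_icer(tt, c1), class = "ptsdcea_model_error")
})

test_that("half-cycle correction halves the first and last modelled cycles", {
  spec <- markov_spec(half_cycle_correction = TRUE)
  plain <- run_cohort_model(markov_spec(), state_values(), "control")
  hcc <- run_cohort_model(spec, state_values(), "control")
  expect_equal(hcc$cost[2], plain$cost[2] / 2)
  expect_equal(hcc$cost[12], plain$cost[12] / 2)
  expect_equal(hcc$cost[3:11], plain$cost[3:11])
})

test_that("markov_cua tabulates both arms by year", {
  out <- markov_cua()
  expect_equal(out$by_year$year, 1:3)
  expect_equal(out$by_year$cost_diff,
               out$by_year$cost_treatment - out$by_year$cost_control)
  expect_equal(tidy(out$treatment)$arm[1], "treatment")
})
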