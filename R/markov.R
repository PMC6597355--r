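#' Convert a probability between time horizons
#'
#' Converts a probability observed over one duration to an equivalent
#' probability over another, via the constant-rate assumption: the
#' probability is turned into an instantaneous rate, the rate rescaled to
#' the new duration, and converted back:
#' `1 - exp(log(1 - p_long) * t_short / t_long)`.
#' A 9-month recovery probability of 0.34 becomes a 3-month probability of
#' 0.129 (to 3 d.p.).
#'
#' @param p_long Probability over `t_long`; must be in \[0, 1).
#' @param t_long,t_short Durations in any common unit; must be positive.
#' @return The probability over `t_short`, full precision.
#' @examples
#' round(convert_probability(0.34, 9, 3), 3) # 0.129
#' @export
convert_probability <- function(p_long, t_long, t_short) {
  if (any(t_long <= 0) || any(t_short <= 0))
    rlang::abort("durations must be positive", class = "ptsdcea_domain_error")
  if (any(p_long < 0 | p_long >= 1))
    rlang::abort("`p_long` must be in [0, 1): p = 1 implies an infinite rate",
                 class = "ptsdcea_domain_error")
  1 - exp(log(1 - p_long) * t_short / t_long)
}

#' Discount factor for a model cycle
#'
#' Costs and QALYs in the first model year are undiscounted; later years are
#' discounted at an annual rate (default 3.5%). With the default
#' `"yearly"` mode every cycle in year y >= 2 shares the factor
#' `1/(1+rate)^(y-1)`; the `"per_cycle"` mode discounts each cycle by the
#' time elapsed since the end of year 1.
#'
#' @param cycle Cycle index (1-based, vectorised).
#' @param cycle_length Cycle length in years (default 0.25).
#' @param rate Annual discount rate (default 0.035).
#' @param mode `"yearly"` (default) or `"per_cycle"`.
#' @return Discount factor(s) in (0, 1\].
#' @export
discount_factor <- function(cycle, cycle_length = 0.25, rate = 0.035,
                            mode = c("yearly", "per_cycle")) {
  mode <- match.arg(mode)
  if (rate < 0)
    rlang::abort("discount rate must be non-negative",
                 class = "ptsdcea_domain_error")
  if (mode == "yearly") {
    year <- ceiling(cycle * cycle_length)
    ifelse(year <= 1, 1, (1 + rate)^-(year - 1))
  } else {
    elapsed <- pmax((cycle - 1) * cycle_length - (1 - cycle_length), 0)
    (1 + rate)^-elapsed
  }
}

#' Per-cycle costs and QALYs of the two health states
#'
#' Three-month cycle values for the PTSD and PTSD-free states: costs of 549
#' and 236 GBP and QALYs of 0.185 and 0.193 per cycle, estimated from the
#' trial (PTSD state from all children at baseline; PTSD-free state from
#' children PTSD-free at follow-up, excluding intervention costs).
#'
#' @param cost_ptsd,cost_free GBP per 3-month cycle.
#' @param qaly_ptsd,qaly_free QALYs per 3-month cycle.
#' @return A named list of class `state_values`.
#' @export
state_values <- function(cost_ptsd = 549, cost_free = 236,
                         qaly_ptsd = 0.185, qaly_free = 0.193) {
  v <- list(cost_ptsd = cost_ptsd, cost_free = cost_free,
            qaly_ptsd = qaly_ptsd, qaly_free = qaly_free)
  if (any(unlist(v) < 0))
    rlang::abort("state values must be non-negative",
                 class = "ptsdcea_config_error")
  structure(v, class = "state_values")
}

#' Specification of the two-state Markov cohort model
#'
#' A cohort enters the model at the end of the trial, split between the PTSD
#' and PTSD-free states according to its arm's recovery proportion. Cycle 1
#' carries the arm's observed trial cost and QALYs. Natural recovery moves
#' PTSD children to the absorbing PTSD-free state at the start of each
#' recovery cycle (default cycles 2-4, i.e. the remainder of year 1) with a
#' per-cycle probability converted from a 9-month meta-analytic estimate
#' (default 0.129); there is no recovery in years 2-3 and no relapse. Costs
#' and QALYs after year 1 are discounted at 3.5% a year.
#'
#' @param initial_ptsd_free Named per-arm probability of entering PTSD-free
#'   (defaults treatment 0.71, control 0.27).
#' @param trial_cost,trial_qaly Named per-arm cycle-1 (trial) totals
#'   (defaults: costs 1686/307 GBP, QALYs 0.1979/0.1823).
#' @param recovery_prob Per-cycle natural recovery probability
#'   (default 0.129).
#' @param recovery_cycles Cycles at whose start recovery applies
#'   (default `2:4`).
#' @param n_cycles Model horizon in cycles including the trial cycle
#'   (default 12, i.e. 3 years).
#' @param cycle_length Cycle length in years (default 0.25).
#' @param discount_rate Annual discount rate (default 0.035).
#' @param discount_mode See [discount_factor()].
#' @param half_cycle_correction Apply a half-cycle correction to the
#'   modelled cycles (off by default).
#' @return A validated list of class `markov_spec`.
#' @export
markov_spec <- function(initial_ptsd_free = c(treatment = 0.71,
                                              control = 0.27),
                        trial_cost = c(treatment = 1686, control = 307),
                        trial_qaly = c(treatment = 0.1979, control = 0.1823),
                        recovery_prob = 0.129,
                        recovery_cycles = 2:4,
                        n_cycles = 12,
                        cycle_length = 0.25,
                        discount_rate = 0.035,
                        discount_mode = "yearly",
                        half_cycle_correction = FALSE) {
  spec <- list(initial_ptsd_free = initial_ptsd_free,
               trial_cost = trial_cost, trial_qaly = trial_qaly,
               recovery_prob = recovery_prob,
               recovery_cycles = recovery_cycles,
               n_cycles = n_cycles, cycle_length = cycle_length,
               discount_rate = discount_rate,
               discount_mode = discount_mode,
               half_cycle_correction = half_cycle_correction)
  if (any(initial_ptsd_free < 0 | initial_ptsd_free > 1))
    config_abort("initial_ptsd_free", "must be probabilities in [0, 1]")
  if (recovery_prob < 0 || recovery_prob > 1)
    config_abort("recovery_prob", "must be a probability in [0, 1]")
  if (n_cycles < 1) config_abort("n_cycles", "must be >= 1")
  if (!all(c("treatment", "control") %in% names(initial_ptsd_free)))
    config_abort("initial_ptsd_free", "must name both arms")
  structure(spec, class = "markov_spec")
}

#' Run the cohort model for one arm
#'
#' Deterministic state-occupancy recursion. Cycle 1 accrues the arm's trial
#' cost and QALYs at the arm's initial state split. In each recovery cycle
#' the PTSD occupancy is multiplied by `1 - recovery_prob` at the start of
#' the cycle (state change before accrual); every modelled cycle then
#' accrues occupancy-weighted, discounted state values. Occupancies are
#' constant after the last recovery cycle; PTSD-free is absorbing.
#'
#' @param spec A [markov_spec()].
#' @param values A [state_values()] list.
#' @param arm `"treatment"` or `"control"`.
#' @return A tibble of class `markov_trajectory`, one row per cycle:
#'   `cycle`, `year`, `occupancy_ptsd`, `occupancy_free`, `discount`,
#'   `cost`, `qaly`, `cum_cost`, `cum_qaly`.
#' @export
run_cohort_model <- function(spec, values = state_values(),
                             arm = c("treatment", "control")) {
  arm <- match.arg(arm)
  p_free0 <- spec$initial_ptsd_free[[arm]]
  n <- spec$n_cycles
  occ_ptsd <- occ_free <- cost <- qaly <- numeric(n)

  occ_ptsd[1] <- 1 - p_free0
  occ_free[1] <- p_free0
  cost[1] <- spec$trial_cost[[arm]]
  qaly[1] <- spec$trial_qaly[[arm]]

  disc <- discount_factor(seq_len(n), spec$cycle_length,
                          spec$discount_rate, spec$discount_mode)
  hcc <- rep(1, n)
  if (spec$half_cycle_correction && n >= 2) hcc[c(2, n)] <- 0.5

  p <- occ_ptsd[1]
  for (k in seq_len(n)[-1]) {
    if (k %in% spec$recovery_cycles) p <- p * (1 - spec$recovery_prob)
    if (p < -1e-12 || p > 1 + 1e-12)
      rlang::abort("state occupancy left [0, 1]",
                   class = "ptsdcea_model_error")
    occ_ptsd[k] <- p
    occ_free[k] <- 1 - p
    cost[k] <- hcc[k] * disc[k] *
      (p * values$cost_ptsd + (1 - p) * values$cost_free)
    qaly[k] <- hcc[k] * disc[k] *
      (p * values$qaly_ptsd + (1 - p) * values$qaly_free)
  }

  out <- tibble::tibble(
    cycle = seq_len(n),
    year = ceiling(seq_len(n) * spec$cycle_length),
    occupancy_ptsd = occ_ptsd,
    occupancy_free = occ_free,
    discount = disc,
    cost = cost,
    qaly = qaly,
    cum_cost = cumsum(cost),
    cum_qaly = cumsum(qaly)
  )
  structure(out, arm = arm, class = c("markov_trajectory", class(out)))
}

trajectory_at_year <- function(trajectory, year) {
  rows <- trajectory[trajectory$year <= year, ]
  if (nrow(rows) == 0)
    rlang::abort("requested year beyond the model horizon",
                 class = "ptsdcea_model_error")
  rows[nrow(rows), c("cum_cost", "cum_qaly")]
}

#' Model-based incremental analysis at a year boundary
#'
#' Takes the cumulative discounted totals of two arm trajectories at the
#' requested year boundary and feeds their differences to [compute_icer()].
#'
#' @param trajectory_treatment,trajectory_control Trajectories from
#'   [run_cohort_model()], run under the same spec.
#' @param year Year boundary (1-3 under the default 12-cycle horizon).
#' @return A `cua_result` with per-arm cumulative totals and the ICER.
#' @export
model_icer <- function(trajectory_treatment, trajectory_control, year = 3) {
  if (nrow(trajectory_treatment) != nrow(trajectory_control))
    rlang::abort("trajectories have mismatched horizons",
                 class = "ptsdcea_model_error")
  tt <- trajectory_at_year(trajectory_treatment, year)
  tc <- trajectory_at_year(trajectory_control, year)
  arms <- tibble::tibble(
    arm = factor(c("treatment", "control"),
                 levels = c("treatment", "control")),
    cost = c(tt$cum_cost, tc$cum_cost),
    qaly = c(tt$cum_qaly, tc$cum_qaly))
  structure(
    list(arms = arms,
         icer = compute_icer(tt$cum_cost - tc$cum_cost,
                             tt$cum_qaly - tc$cum_qaly),
         analysis_set = sprintf("model_year_%d", year)),
    class = "cua_result")
}

#' Run both arms and summarise by year
#'
#' Convenience wrapper running [run_cohort_model()] for both arms and
#' tabulating cumulative costs, QALYs, their differences and the ICER at
#' each year boundary.
#'
#' @inheritParams run_cohort_model
#' @return A list with `treatment` and `control` trajectories and a
#'   `by_year` tibble (`year`, `cost_treatment`, `cost_control`,
#'   `cost_diff`, `qaly_treatment`, `qaly_control`, `qaly_diff`, `icer`).
#' @export
markov_cua <- function(spec = markov_spec(), values = state_values()) {
  tt <- run_cohort_model(spec, values, "treatment")
  tc <- run_cohort_model(spec, values, "control")
  years <- sort(unique(tt$year))
  by_year <- purrr::map_dfr(years, function(y) {
    a <- trajectory_at_year(tt, y); b <- trajectory_at_year(tc, y)
    tibble::tibble(year = y,
                   cost_treatment = a$cum_cost, cost_control = b$cum_cost,
                   cost_diff = a$cum_cost - b$cum_cost,
                   qaly_treatment = a$cum_qaly, qaly_control = b$cum_qaly,
                   qaly_diff = a$cum_qaly - b$cum_qaly,
                   icer = (a$cum_cost - b$cum_cost) /
                     (a$cum_qaly - b$cum_qaly))
  })
  list(treatment = tt, control = tc, by_year = by_year)
}

#' Microsimulation cross-check of the cohort model
#'
#' Simulates individual patients through the same transition schedule
#' (initial Bernoulli state split, per-cycle recovery in the recovery
#' cycles, absorbing PTSD-free state) and averages their discounted costs
#' and QALYs. Converges to the cohort-model totals as the number of
#' simulated individuals grows; used as an independent oracle in tests.
#'
#' @inheritParams run_cohort_model
#' @param n_patients Number of simulated individuals.
#' @param seed Integer seed.
#' @return A tibble with mean `cum_cost` and `cum_qaly` at the horizon.
#' @export
microsimulate_arm <- function(spec, values = state_values(),
                              arm = c("treatment", "control"),
                              n_patients = 1e5, seed = 1L) {
  arm <- match.arg(arm)
  withr::local_seed(seed)
  n <- spec$n_cycles
  ptsd <- stats::rbinom(n_patients, 1, 1 - spec$initial_ptsd_free[[arm]])
  disc <- discount_factor(seq_len(n), spec$cycle_length,
                          spec$discount_rate, spec$discount_mode)
  cost <- rep(spec$trial_cost[[arm]], n_patients)
  qaly <- rep(spec$trial_qaly[[arm]], n_patients)
  for (k in seq_len(n)[-1]) {
    if (k %in% spec$recovery_cycles) {
      recover <- stats::rbinom(n_patients, 1, spec$recovery_prob)
      ptsd <- ptsd * (1 - recover)
    }
    cost <- cost + disc[k] *
      ifelse(ptsd == 1, values$cost_ptsd, values$cost_free)
    qaly <- qaly + disc[k] *
      ifelse(ptsd == 1, values$qaly_ptsd, values$qaly_free)
  }
  tibble::tibble(cum_cost = mean(cost), cum_qaly = mean(qaly))
}
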