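#' Fit a Beta distribution to a mean and 95% interval
#'
#' Finds Beta shape parameters whose mean and 2.5%/97.5% quantiles best
#' match the given summary, by least squares on the two quantiles with the
#' mean as a soft constraint. Used to sample a proportion whose published
#' summary is a mean with a 95% CI rather than explicit shape parameters.
#'
#' @param mean Target mean in (0, 1).
#' @param lower,upper Target 95% interval bounds.
#' @return Named vector `c(shape1, shape2)`.
#' @export
beta_from_ci <- function(mean, lower, upper) {
  stopifnot(mean > 0, mean < 1, lower < mean, mean < upper, upper < 1)
  obj <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    (stats::qbeta(0.025, a, b) - lower)^2 +
      (stats::qbeta(0.975, a, b) - upper)^2 +
      (a / (a + b) - mean)^2
  }
  # moment-matched start
  v <- ((upper - lower) / 3.92)^2
  k <- mean * (1 - mean) / v - 1
  fit <- stats::optim(log(c(mean * k, (1 - mean) * k)), obj)
  c(shape1 = exp(fit$par[1]), shape2 = exp(fit$par[2]))
}

#' Default parameter distributions for the probabilistic sensitivity analysis
#'
#' The published uncertainty distributions: arm efficacies (probability of
#' being PTSD-free at trial follow-up) Beta(19, 7) and Beta(3, 9); state
#' costs Gamma(19.532, scale 28.118) and Gamma(10.369, scale 22.738) whose
#' means reproduce the 549 and 236 GBP point values; per-cycle state QALYs
#' as Betas. The two published QALY Betas are assigned to the state whose
#' stated mean each matches — Beta(808, 3567) (mean 0.1847) to the PTSD
#' state (stated 0.185) and Beta(2618, 10940) (mean 0.1931) to the
#' PTSD-free state (stated 0.193) — i.e. the printed assignment is swapped;
#' a warning notes this.
#'
#' Natural recovery is sampled on the 9-month scale from a Beta fitted to
#' the published mean 34% and 95% CI (21%, 49%) ([beta_from_ci()]) and
#' converted per draw to a 3-month probability. Set
#' `remission_scale = "three_month"` to instead draw Beta(14, 95)
#' (mean 0.128) directly on the 3-month scale.
#'
#' Each component is a list `list(dist, ...)` with `dist` one of `"beta"`
#' (`shape1`, `shape2`), `"gamma"` (`shape`, `scale`), `"fixed"` (`value`);
#' the remission component additionally carries `horizon_months`. Replacing
#' every component with `"fixed"` values collapses the PSA to the
#' deterministic model.
#'
#' @param remission_scale `"nine_month"` (default) or `"three_month"`.
#' @param quiet Suppress the QALY-assignment warning.
#' @return A named list of distribution specifications.
#' @export
psa_distributions <- function(remission_scale = c("nine_month",
                                                  "three_month"),
                              quiet = FALSE) {
  remission_scale <- match.arg(remission_scale)
  if (!quiet)
    rlang::warn(paste(
      "state-QALY Betas assigned by stated means: Beta(808, 3567) -> PTSD,",
      "Beta(2618, 10940) -> PTSD-free (published assignment swapped)"),
      class = "ptsdcea_qaly_beta_swap", .frequency = "once",
      .frequency_id = "ptsdcea_qaly_beta_swap")
  remission <- if (remission_scale == "nine_month") {
    fit <- beta_from_ci(0.34, 0.21, 0.49)
    list(dist = "beta", shape1 = fit[["shape1"]], shape2 = fit[["shape2"]],
         horizon_months = 9)
  } else {
    list(dist = "beta", shape1 = 14, shape2 = 95, horizon_months = 3)
  }
  list(
    efficacy_treatment = list(dist = "beta", shape1 = 19, shape2 = 7),
    efficacy_control = list(dist = "beta", shape1 = 3, shape2 = 9),
    remission = remission,
    cost_ptsd = list(dist = "gamma", shape = 19.532, scale = 28.118),
    cost_free = list(dist = "gamma", shape = 10.369, scale = 22.738),
    qaly_ptsd = list(dist = "beta", shape1 = 808, shape2 = 3567),
    qaly_free = list(dist = "beta", shape1 = 2618, shape2 = 10940)
  )
}

#' Fixed-value distributions collapsing the PSA to the deterministic model
#'
#' @param spec A [markov_spec()] supplying the deterministic efficacies and
#'   recovery probability.
#' @param values A [state_values()] list.
#' @return A distribution list of `"fixed"` components.
#' @export
degenerate_distributions <- function(spec = markov_spec(),
                                     values = state_values()) {
  fx <- function(v) list(dist = "fixed", value = v)
  list(
    efficacy_treatment = fx(spec$initial_ptsd_free[["treatment"]]),
    efficacy_control = fx(spec$initial_ptsd_free[["control"]]),
    remission = c(fx(spec$recovery_prob), horizon_months = 3),
    cost_ptsd = fx(values$cost_ptsd),
    cost_free = fx(values$cost_free),
    qaly_ptsd = fx(values$qaly_ptsd),
    qaly_free = fx(values$qaly_free)
  )
}

draw_param <- function(n, d) {
  switch(d$dist,
         beta = stats::rbeta(n, d$shape1, d$shape2),
         gamma = stats::rgamma(n, shape = d$shape, scale = d$scale),
         fixed = rep(d$value, n),
         rlang::abort(sprintf("unknown distribution type `%s`", d$dist),
                      class = "ptsdcea_config_error"))
}

# vectorised over draws: cumulative cost/QALY for one arm at each year
psa_run_arm <- function(p_free0, trial_cost, trial_qaly, r3,
                        cost_ptsd, cost_free, qaly_ptsd, qaly_free, spec) {
  n <- length(p_free0)
  p <- 1 - p_free0
  cost <- rep(trial_cost, n)
  qaly <- rep(trial_qaly, n)
  disc <- discount_factor(seq_len(spec$n_cycles), spec$cycle_length,
                          spec$discount_rate, spec$discount_mode)
  years <- ceiling(seq_len(spec$n_cycles) * spec$cycle_length)
  out_cost <- out_qaly <- matrix(NA_real_, n, max(years))
  for (k in seq_len(spec$n_cycles)) {
    if (k > 1) {
      if (k %in% spec$recovery_cycles) p <- p * (1 - r3)
      cost <- cost + disc[k] * (p * cost_ptsd + (1 - p) * cost_free)
      qaly <- qaly + disc[k] * (p * qaly_ptsd + (1 - p) * qaly_free)
    }
    out_cost[, years[k]] <- cost
    out_qaly[, years[k]] <- qaly
  }
  list(cost = out_cost, qaly = out_qaly)
}

#' Sample the probabilistic sensitivity analysis
#'
#' Draws `n_draws` independent parameter vectors from `distributions`,
#' re-runs both arms' cohort models per draw (sampled initial efficacies,
#' sampled per-cycle remission, sampled state values; trial-cycle costs and
#' QALYs held fixed at their observed values), and records incremental
#' costs and QALYs at each year boundary together with the year-3
#' cost-effectiveness-plane quadrant. Fully reproducible from the seed.
#'
#' @param n_draws Number of draws (default 5000).
#' @param seed Integer seed.
#' @param spec A [markov_spec()].
#' @param distributions A [psa_distributions()] list.
#' @return A tibble of class `psa_draws`: `draw`, the seven sampled
#'   parameters (`remission_3m` on the per-cycle scale), `delta_cost_y1` ..
#'   `delta_qaly_y3`, `quadrant`.
#' @export
sample_psa <- function(n_draws = 5000, seed = 1L, spec = markov_spec(),
                       distributions = psa_distributions(quiet = TRUE)) {
  if (n_draws < 1) config_abort("n_draws", "must be >= 1")
  withr::local_seed(seed)
  et <- draw_param(n_draws, distributions$efficacy_treatment)
  ec <- draw_param(n_draws, distributions$efficacy_control)
  rem <- draw_param(n_draws, distributions$remission)
  hm <- distributions$remission$horizon_months
  r3 <- if (hm == 3) rem else convert_probability(rem, hm, 3)
  cp <- draw_param(n_draws, distributions$cost_ptsd)
  cf <- draw_param(n_draws, distributions$cost_free)
  qp <- draw_param(n_draws, distributions$qaly_ptsd)
  qf <- draw_param(n_draws, distributions$qaly_free)

  tr <- psa_run_arm(et, spec$trial_cost[["treatment"]],
                    spec$trial_qaly[["treatment"]], r3, cp, cf, qp, qf, spec)
  co <- psa_run_arm(ec, spec$trial_cost[["control"]],
                    spec$trial_qaly[["control"]], r3, cp, cf, qp, qf, spec)
  dcost <- tr$cost - co$cost
  dqaly <- tr$qaly - co$qaly
  n_years <- ncol(dcost)

  out <- tibble::tibble(
    draw = seq_len(n_draws),
    efficacy_treatment = et, efficacy_control = ec, remission_3m = r3,
    cost_ptsd = cp, cost_free = cf, qaly_ptsd = qp, qaly_free = qf)
  for (y in seq_len(n_years)) {
    out[[paste0("delta_cost_y", y)]] <- dcost[, y]
    out[[paste0("delta_qaly_y", y)]] <- dqaly[, y]
  }
  dc <- dcost[, n_years]; de <- dqaly[, n_years]
  out$quadrant <- dplyr::case_when(
    dc < 0 & de > 0 ~ "dominant",
    dc > 0 & de < 0 ~ "dominated",
    dc >= 0 & de >= 0 ~ "NE",
    TRUE ~ "SW")
  structure(out, horizon_years = n_years,
            class = c("psa_draws", class(out)))
}

#' Threshold grid for the acceptability curve
#'
#' 0 to 50,000 GBP/QALY in 500 GBP steps, which includes the 20,000 and
#' 30,000 GBP/QALY decision anchors.
#' @return Numeric vector of willingness-to-pay thresholds.
#' @export
ceac_thresholds <- function() seq(0, 50000, by = 500)

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold lambda the curve gives the
#' probability that treatment is cost-effective: the fraction of PSA draws
#' with positive net monetary benefit, `lambda * dE - dC > 0`.
#'
#' @param draws A [sample_psa()] tibble.
#' @param thresholds Willingness-to-pay grid in GBP/QALY.
#' @param year Year boundary at which deltas are evaluated (default the
#'   draw horizon).
#' @return A tibble of class `ceac_curve`: `threshold`, `probability`.
#' @export
ceac <- function(draws, thresholds = ceac_thresholds(), year = NULL) {
  if (nrow(draws) == 0)
    rlang::abort("CEAC needs at least one draw",
                 class = "ptsdcea_analysis_error")
  if (is.null(year)) year <- attr(draws, "horizon_years") %||% 3
  dc <- draws[[paste0("delta_cost_y", year)]]
  de <- draws[[paste0("delta_qaly_y", year)]]
  prob <- purrr::map_dbl(thresholds, function(l) mean(l * de - dc > 0))
  structure(tibble::tibble(threshold = thresholds, probability = prob),
            year = year, class = c("ceac_curve", class(tibble::tibble())))
}

#' Amortize a one-off training cost over its service life
#'
#' Straight-line amortization of a total training outlay over an assumed
#' number of years and annual patient caseload:
#' `total / (years * caseload)` GBP per treated patient. The resulting
#' per-patient amount is added to the treatment arm's cycle-1 cost in the
#' training-cost sensitivity analysis.
#'
#' @param total_training_cost Total outlay in GBP.
#' @param years Service life in years (default 5).
#' @param annual_caseload Patients treated per year (default 29, the trial's
#'   annual recruitment).
#' @return GBP per treated patient.
#' @examples
#' amortize_training(26970) # 186
#' @export
amortize_training <- function(total_training_cost, years = 5,
                              annual_caseload = 29) {
  if (total_training_cost < 0 || years <= 0 || annual_caseload <= 0)
    rlang::abort("amortization inputs must be positive",
                 class = "ptsdcea_domain_error")
  total_training_cost / (years * annual_caseload)
}

#' One-way sensitivity-analysis variants
#'
#' Returns the model spec and state values under a named variant:
#' `"base"` (unchanged), `"training_costs"` (the amortized per-patient
#' training cost, default 186 GBP, added to the treatment arm's cycle-1
#' cost) or `"complete_case"` (initial PTSD-free proportions 0.90/0.18 and
#' PTSD-free cycle values 264.55 GBP / 0.2027 QALYs, as estimated from
#' complete cases only).
#'
#' @param variant One of `"base"`, `"training_costs"`, `"complete_case"`.
#' @param spec Base [markov_spec()].
#' @param values Base [state_values()].
#' @param training_cost_per_patient Per-patient amortized training cost.
#' @return A list with elements `spec` and `values`.
#' @export
variant_inputs <- function(variant = c("base", "training_costs",
                                       "complete_case"),
                           spec = markov_spec(), values = state_values(),
                           training_cost_per_patient = amortize_training(26970)) {
  variant <- match.arg(variant)
  if (variant == "training_costs") {
    spec$trial_cost[["treatment"]] <-
      spec$trial_cost[["treatment"]] + training_cost_per_patient
  } else if (variant == "complete_case") {
    spec$initial_ptsd_free <- c(treatment = 0.90, control = 0.18)
    values$cost_free <- 264.55
    values$qaly_free <- 0.2027
  }
  list(spec = spec, values = values)
}

#' Run a one-way sensitivity variant end to end
#'
#' Re-runs the deterministic cohort model and the PSA under a variant's
#' parameter overrides and returns the deterministic result, the draws and
#' the acceptability curve.
#'
#' @inheritParams variant_inputs
#' @param n_draws,seed PSA settings, see [sample_psa()].
#' @param distributions A [psa_distributions()] list.
#' @param year Year boundary for the deterministic result and CEAC.
#' @return A list: `variant`, `deterministic` (a `cua_result`), `draws`,
#'   `ceac`.
#' @export
one_way_variant <- function(variant = c("base", "training_costs",
                                        "complete_case"),
                            spec = markov_spec(), values = state_values(),
                            n_draws = 5000, seed = 1L,
                            distributions = psa_distributions(quiet = TRUE),
                            year = 3) {
  variant <- match.arg(variant)
  inp <- variant_inputs(variant, spec, values)
  tt <- run_cohort_model(inp$spec, inp$values, "treatment")
  tc <- run_cohort_model(inp$spec, inp$values, "control")
  det <- model_icer(tt, tc, year)
  draws <- sample_psa(n_draws, seed, inp$spec, distributions)
  list(variant = variant, deterministic = det, draws = draws,
       ceac = ceac(draws, year = year))
}
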