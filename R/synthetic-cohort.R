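#' Default resource-use generator parameters
#'
#' Per-category parameters for the zero-inflated, right-skewed resource-use
#' counts drawn by [generate_cohort()]. Together with the packaged unit-cost
#' table ([default_unit_costs()]) these produce per-category cost
#' distributions with many exact zeros and long right tails, the pattern
#' typical of child mental-health service-use data.
#'
#' @return A tibble with columns `category`, `mean_count` (expected count per
#'   assessment period) and `zero_prob` (structural zero-inflation
#'   probability).
#' @export
default_cost_category_params <- function() {
  tibble::tribble(
    ~category,                  ~mean_count, ~zero_prob,
    "outpatient",               0.5,         0.70,
    "emergency_dept",           0.25,        0.80,
    "ambulance",                0.2,         0.80,
    "gp_surgery",               2.0,         0.35,
    "gp_home_visit",            0.8,         0.65,
    "district_nurse",           0.4,         0.80,
    "counsellor",               1.0,         0.60,
    "educational_psychologist", 0.3,         0.85,
    "social_services",          0.8,         0.70,
    "medications",              1.5,         0.55
  )
}

#' Configuration for the synthetic trial cohort generator
#'
#' Encodes the statistical structure of the two-arm early-therapy trial the
#' downstream analysis assumes: small unequal arms, arm-specific recovery
#' (PTSD-free) proportions at follow-up, SDQ subscale scores whose mapped
#' utilities separate recovered from non-recovered children, zero-heavy
#' right-skewed resource use, therapist contact minutes for the treated arm
#' only, and completely-at-random follow-up missingness.
#'
#' @param n_treatment,n_control Arm sizes (defaults 14 and 15).
#' @param recovery_prob_treatment,recovery_prob_control Probability of being
#'   PTSD-free at follow-up per arm (defaults 0.71 and 0.27).
#' @param baseline_utility_mean Target mean mapped utility at baseline, when
#'   every child has PTSD (default 0.734).
#' @param recovered_utility_mean Target mean mapped utility for children
#'   PTSD-free at follow-up (default 0.925); non-recovered children keep the
#'   baseline utility profile.
#' @param followup_missing_prob Probability that a record's entire follow-up
#'   block is missing (default 0.2).
#' @param contact_minutes_mean Mean therapist contact time, treated arm, in
#'   minutes (default 636.25).
#' @param contact_minutes_range Attainable range of contact minutes
#'   (default `c(195, 755)`).
#' @param cost_category_params Resource-use parameters, see
#'   [default_cost_category_params()].
#' @param cost_outcome_correlation Optional correlation knob in \[0, 1\]
#'   linking follow-up resource use to recovery status (0 = independence
#'   given recovery status, the default; positive values inflate
#'   non-recovered children's counts and deflate recovered children's by the
#'   same expected factor).
#' @param age_range Inclusive integer age range (default 8-17).
#' @param seed Mandatory integer seed.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_treatment = 14, n_control = 15,
                          recovery_prob_treatment = 0.71,
                          recovery_prob_control = 0.27,
                          baseline_utility_mean = 0.734,
                          recovered_utility_mean = 0.925,
                          followup_missing_prob = 0.2,
                          contact_minutes_mean = 636.25,
                          contact_minutes_range = c(195, 755),
                          cost_category_params = default_cost_category_params(),
                          cost_outcome_correlation = 0,
                          age_range = c(8, 17),
                          seed = NULL) {
  cfg <- list(
    n_treatment = n_treatment, n_control = n_control,
    recovery_prob_treatment = recovery_prob_treatment,
    recovery_prob_control = recovery_prob_control,
    baseline_utility_mean = baseline_utility_mean,
    recovered_utility_mean = recovered_utility_mean,
    followup_missing_prob = followup_missing_prob,
    contact_minutes_mean = contact_minutes_mean,
    contact_minutes_range = contact_minutes_range,
    cost_category_params = tibble::as_tibble(cost_category_params),
    cost_outcome_correlation = cost_outcome_correlation,
    age_range = age_range,
    seed = seed
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

config_abort <- function(field, msg) {
  rlang::abort(sprintf("Invalid `%s`: %s", field, msg),
               class = "ptsdcea_config_error")
}

validate_cohort_config <- function(cfg) {
  for (f in c("n_treatment", "n_control")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 ||
        cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      config_abort(f, "must be a single integer >= 1")
  }
  for (f in c("recovery_prob_treatment", "recovery_prob_control",
              "followup_missing_prob", "cost_outcome_correlation")) {
    p <- cfg[[f]]
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
      config_abort(f, "must be a probability in [0, 1]")
  }
  for (f in c("baseline_utility_mean", "recovered_utility_mean")) {
    u <- cfg[[f]]
    if (!is.numeric(u) || length(u) != 1 || u < 0.51 || u > 0.93)
      config_abort(f, "must lie in [0.51, 0.93], the range of the SDQ-CHU-9D mapping")
  }
  if (!is.numeric(cfg$contact_minutes_mean) || cfg$contact_minutes_mean < 0)
    config_abort("contact_minutes_mean", "must be non-negative")
  r <- cfg$contact_minutes_range
  if (!is.numeric(r) || length(r) != 2 || r[1] > r[2] || r[1] < 0)
    config_abort("contact_minutes_range", "bounds must be ordered and non-negative")
  if (cfg$contact_minutes_mean < r[1] || cfg$contact_minutes_mean > r[2])
    config_abort("contact_minutes_mean", "must lie inside contact_minutes_range")
  ccp <- cfg$cost_category_params
  if (!all(c("category", "mean_count", "zero_prob") %in% names(ccp)))
    config_abort("cost_category_params",
                 "needs columns category, mean_count, zero_prob")
  if (any(ccp$mean_count < 0))
    config_abort("cost_category_params", "mean_count must be >= 0")
  if (any(ccp$zero_prob < 0 | ccp$zero_prob > 1))
    config_abort("cost_category_params", "zero_prob must be in [0, 1]")
  a <- cfg$age_range
  if (!is.numeric(a) || length(a) != 2 || a[1] > a[2])
    config_abort("age_range", "bounds must be ordered")
  if (is.null(cfg$seed) || !is.numeric(cfg$seed) || length(cfg$seed) != 1 ||
      is.na(cfg$seed) || cfg$seed != round(cfg$seed))
    config_abort("seed", "a single integer seed is mandatory")
  invisible(cfg)
}

# Problem-subscale means scaled so the mapped utility mean hits the target.
# Reference problem profile (emotion, conduct, hyper, peer) = (6, 3, 5, 4)
# with prosocial mean 6; the scale factor s solves
#   intercept + 0.005 * prosocial - s * sum(|w_j| * m_j) = target.
sdq_profile_for_utility <- function(target, coeffs = chu9d_coefficients(),
                                    prosocial_mean = NULL) {
  ref <- c(emotion = 6, conduct = 3, hyper = 5, peer = 4)
  if (is.null(prosocial_mean)) {
    # richer prosocial behaviour for healthier targets
    prosocial_mean <- if (target >= 0.85) 9.8 else 6
  }
  w <- abs(coeffs[c("emotion", "conduct", "hyper", "peer")])
  s <- (coeffs[["intercept"]] + coeffs[["prosocial"]] * prosocial_mean -
          target) / sum(w * ref)
  if (s < 0 || any(s * ref > 10))
    rlang::abort("utility target outside the attainable SDQ profile range",
                 class = "ptsdcea_config_error")
  c(s * ref, prosocial = prosocial_mean)
}

draw_sdq <- function(n, profile) {
  out <- purrr::imap(as.list(profile), function(m, nm) {
    stats::rbinom(n, size = 10, prob = m / 10)
  })
  names(out) <- paste0("sdq_", names(profile))
  tibble::as_tibble(out)
}

draw_counts <- function(n, params, inflate = 1) {
  out <- purrr::pmap(params, function(category, mean_count, zero_prob, ...) {
    mu <- inflate * mean_count / max(1 - zero_prob, 1e-12)
    nonzero <- stats::runif(n) >= zero_prob
    cnt <- stats::rnbinom(n, size = 1, mu = mu)  # geometric: right-skewed
    as.integer(nonzero) * cnt
  })
  names(out) <- paste0("res_", params$category)
  tibble::as_tibble(out)
}

#' Generate a seeded synthetic trial cohort
#'
#' Draws one patient-level dataset with the structure described in
#' [cohort_config()]: every child enters with PTSD; follow-up PTSD status is
#' Bernoulli per arm; follow-up SDQ scores are drawn conditionally on
#' recovery status so recovered children map to higher utilities;
#' resource-use counts are zero-inflated geometric draws; contact minutes
#' (treated arm only) follow a scaled Beta on the configured range. The
#' follow-up block is then masked completely at random via
#' [apply_missingness()]. Identical configs (including seed) give
#' byte-identical output.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per child: `id`, `arm`, `age`, `gender`,
#'   `ptsd_baseline`, `ptsd_followup`, ten `sdq_*` columns (five subscales at
#'   baseline and follow-up), paired `res_*_baseline`/`res_*_followup` count
#'   columns, `contact_minutes`, and a `followup_missing` flag.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  withr::local_seed(config$seed)

  n <- config$n_treatment + config$n_control
  arm <- factor(rep(c("treatment", "control"),
                    c(config$n_treatment, config$n_control)),
                levels = c("treatment", "control"))

  base_prof <- sdq_profile_for_utility(config$baseline_utility_mean)
  rec_prof <- sdq_profile_for_utility(config$recovered_utility_mean)

  recovery_p <- ifelse(arm == "treatment",
                       config$recovery_prob_treatment,
                       config$recovery_prob_control)
  recovered <- stats::rbinom(n, 1, recovery_p) == 1

  sdq_base <- draw_sdq(n, base_prof)
  names(sdq_base) <- paste0(names(sdq_base), "_baseline")
  sdq_fu_rec <- draw_sdq(n, rec_prof)
  sdq_fu_not <- draw_sdq(n, base_prof)
  sdq_fu <- purrr::map2(sdq_fu_rec, sdq_fu_not,
                        function(a, b) ifelse(recovered, a, b))
  sdq_fu <- tibble::as_tibble(sdq_fu)
  names(sdq_fu) <- paste0(names(sdq_fu_rec), "_followup")

  res_base <- draw_counts(n, config$cost_category_params)
  names(res_base) <- paste0(names(res_base), "_baseline")
  # optional dependence of follow-up service use on recovery status
  rho <- config$cost_outcome_correlation
  inflate <- ifelse(recovered, 1 - rho / 2, 1 + rho / 2)
  res_fu <- draw_counts(n, config$cost_category_params)
  if (rho > 0) {
    res_fu <- tibble::as_tibble(purrr::map(res_fu, function(cnt) {
      extra <- stats::rbinom(n, size = cnt, prob = pmin(abs(inflate - 1), 1))
      pmax(cnt + ifelse(inflate >= 1, extra, -extra), 0L)
    }))
  }
  names(res_fu) <- sub("_baseline$", "", names(res_base))
  names(res_fu) <- paste0(names(res_fu), "_followup")

  lo <- config$contact_minutes_range[1]
  hi <- config$contact_minutes_range[2]
  if (hi > lo) {
    m <- (config$contact_minutes_mean - lo) / (hi - lo)
    kappa <- 7  # concentration of the scaled-Beta contact-time draw
    minutes <- lo + (hi - lo) * stats::rbeta(n, kappa * m, kappa * (1 - m))
  } else {
    minutes <- rep(lo, n)
  }
  minutes[arm == "control"] <- 0

  records <- dplyr::bind_cols(
    tibble::tibble(
      id = sprintf("P%03d", seq_len(n)),
      arm = arm,
      age = sample(seq(config$age_range[1], config$age_range[2]), n,
                   replace = TRUE),
      gender = factor(sample(c("female", "male"), n, replace = TRUE),
                      levels = c("female", "male")),
      ptsd_baseline = TRUE,
      ptsd_followup = !recovered
    ),
    sdq_base, sdq_fu, res_base, res_fu,
    tibble::tibble(contact_minutes = minutes)
  )

  apply_missingness(records, config$followup_missing_prob,
                    seed = config$seed + 1L)
}

followup_columns <- function(records) {
  c("ptsd_followup",
    grep("^(sdq|res)_.*_followup$", names(records), value = TRUE))
}

#' Mask follow-up data completely at random
#'
#' Independently masks each record's entire follow-up block (`ptsd_followup`
#' and every `sdq_*_followup` / `res_*_followup` column) with probability
#' `prob`, emulating questionnaire non-completion and loss to follow-up.
#' Baseline fields are never masked; a `followup_missing` flag records the
#' masking.
#'
#' @param records A patient-record tibble.
#' @param prob Masking probability in \[0, 1\].
#' @param seed Integer seed.
#' @return `records` with masked follow-up fields and a `followup_missing`
#'   column.
#' @export
apply_missingness <- function(records, prob, seed) {
  if (!is.numeric(prob) || length(prob) != 1 || prob < 0 || prob > 1)
    config_abort("prob", "must be a probability in [0, 1]")
  withr::local_seed(seed)
  mask <- stats::runif(nrow(records)) < prob
  cols <- followup_columns(records)
  records[mask, cols] <- NA
  dplyr::mutate(records, followup_missing = mask)
}

#' Read or write a cohort as CSV
#'
#' Patient records are exchanged as plain CSV with the documented header;
#' missing values are empty fields.
#'
#' @param records A patient-record tibble.
#' @param path File path.
#' @return `write_cohort()` returns `records` invisibly; `read_cohort()`
#'   returns the tibble with `arm`/`gender` restored as factors.
#' @export
write_cohort <- function(records, path) {
  readr::write_csv(records, path, na = "")
  invisible(records)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  records <- readr::read_csv(path, na = "", show_col_types = FALSE)
  dplyr::mutate(
    records,
    arm = factor(.data$arm, levels = c("treatment", "control")),
    gender = factor(.data$gender, levels = c("female", "male"))
  )
}

#' Read or write a cohort configuration as YAML
#'
#' @param config A [cohort_config()].
#' @param path File path.
#' @return `read_cohort_config()` returns a validated [cohort_config()].
#' @export
write_cohort_config <- function(config, path) {
  x <- unclass(config)
  x$cost_category_params <- as.list(x$cost_category_params)
  yaml::write_yaml(x, path)
  invisible(config)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$cost_category_params <- tibble::as_tibble(x$cost_category_params)
  do.call(cohort_config, x)
}
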