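#' Build the per-patient analysis table for the trial horizon
#'
#' Combines mapped utilities ([add_utilities()]) and priced resource use
#' ([aggregate_costs()]) into the per-patient table the trial analysis works
#' on, and accrues QALYs over the 11-week trial window by trapezoidal
#' interpolation between the baseline and follow-up utilities.
#'
#' @inheritParams aggregate_costs
#' @param coeffs Mapping coefficients, see [chu9d_coefficients()].
#' @param window_years Length of the QALY accrual window in years.
#' @return A tibble: `id`, `arm`, `age`, `gender`, `followup_missing`,
#'   `cost_baseline`, `cost_followup`, `utility_baseline`,
#'   `utility_followup`, `qaly`.
#' @export
trial_analysis_table <- function(records, unit_costs = default_unit_costs(),
                                 hourly_rate = 138,
                                 exclude_index_trauma = TRUE,
                                 coeffs = chu9d_coefficients(),
                                 window_years = trial_window_years()) {
  costs <- aggregate_costs(records, unit_costs, hourly_rate,
                           exclude_index_trauma)
  add_utilities(records, coeffs) |>
    dplyr::select(dplyr::all_of(c("id", "arm", "age", "gender",
                                  "followup_missing", "utility_baseline",
                                  "utility_followup"))) |>
    dplyr::left_join(
      dplyr::select(costs, dplyr::all_of(c("id", "total_cost_baseline",
                                           "total_cost_followup"))),
      by = "id") |>
    dplyr::rename(cost_baseline = "total_cost_baseline",
                  cost_followup = "total_cost_followup") |>
    dplyr::mutate(qaly = accrue_qalys(.data$utility_baseline,
                                      .data$utility_followup,
                                      window_years))
}

impute_one <- function(tbl, outcome, baseline, seed, add_noise) {
  miss <- is.na(tbl[[outcome]])
  if (!any(miss)) return(tbl)
  obs <- tbl[!miss, ]
  for (p in c(baseline, "age")) {
    if (all(is.na(obs[[p]])))
      rlang::abort(sprintf("predictor `%s` is entirely missing", p),
                   class = "ptsdcea_imputation_error")
  }
  fml <- stats::reformulate(c("arm", baseline, "age", "gender"),
                            response = outcome)
  fit <- stats::lm(fml, data = obs)
  pred <- stats::predict(fit, newdata = tbl[miss, ])
  if (add_noise) {
    withr::local_seed(seed)
    pred <- pred + stats::rnorm(sum(miss), 0, stats::sigma(fit))
  }
  tbl[[outcome]][miss] <- pred
  tbl
}

#' Conditional-regression imputation of missing follow-up data
#'
#' Missing follow-up costs and utilities are replaced by predictions from a
#' linear regression on arm, the corresponding baseline value, age and
#' gender, fitted to the complete records. Single deterministic imputation
#' (the predicted value, no noise) is the default; seeded residual noise can
#' be added. Observed values are never altered; QALYs are re-accrued after
#' imputation.
#'
#' @param tbl A [trial_analysis_table()].
#' @param seed Integer seed (used only when `add_noise = TRUE`).
#' @param add_noise Add Gaussian residual noise to imputed values.
#' @param window_years QALY window used to re-accrue after imputation.
#' @return `tbl` with no missing `cost_followup`, `utility_followup` or
#'   `qaly` fields.
#' @export
impute_missing <- function(tbl, seed = 1L, add_noise = FALSE,
                           window_years = trial_window_years()) {
  tbl <- impute_one(tbl, "cost_followup", "cost_baseline", seed, add_noise)
  tbl <- impute_one(tbl, "utility_followup", "utility_baseline",
                    seed + 1L, add_noise)
  dplyr::mutate(tbl, qaly = accrue_qalys(.data$utility_baseline,
                                         .data$utility_followup,
                                         window_years))
}

#' Covariate-adjusted between-arm difference
#'
#' Regresses the follow-up outcome on treatment group, the corresponding
#' baseline value, age and gender, and returns the group coefficient
#' (treatment minus control). The default is an identity-link Gaussian
#' model, so the coefficient is a difference in GBP or QALYs; a Gamma
#' log-link alternative is available for strictly positive costs.
#'
#' @param tbl A completed (or complete-case) [trial_analysis_table()].
#' @param outcome `"cost"` or `"qaly"`.
#' @param family `"gaussian"` (identity link, default) or `"gamma"`
#'   (log link; group effect returned on the response scale as a difference
#'   of adjusted predictions).
#' @return The adjusted between-arm difference (scalar).
#' @export
adjust_difference <- function(tbl, outcome = c("cost", "qaly"),
                              family = c("gaussian", "gamma")) {
  outcome <- match.arg(outcome)
  family <- match.arg(family)
  resp <- if (outcome == "cost") "cost_followup" else "qaly"
  base <- if (outcome == "cost") "cost_baseline" else "utility_baseline"
  dat <- tbl[stats::complete.cases(tbl[c(resp, base, "arm", "age",
                                         "gender")]), ]
  if (length(unique(dat$arm)) < 2)
    rlang::abort("both arms must be non-empty",
                 class = "ptsdcea_analysis_error")
  dat$arm <- stats::relevel(factor(dat$arm), ref = "control")
  fml <- stats::reformulate(c("arm", base, "age", "gender"), response = resp)
  if (family == "gaussian") {
    fit <- stats::lm(fml, data = dat)
    qr_rank <- fit$rank
    if (qr_rank < length(stats::coef(fit)))
      rlang::abort("singular design matrix in adjustment model",
                   class = "ptsdcea_analysis_error")
    unname(stats::coef(fit)[["armtreatment"]])
  } else {
    fit <- stats::glm(fml, data = dat,
                      family = stats::Gamma(link = "log"))
    nd <- dat
    nd$arm <- factor("treatment", levels = levels(dat$arm))
    mu1 <- mean(stats::predict(fit, newdata = nd, type = "response"))
    nd$arm <- factor("control", levels = levels(dat$arm))
    mu0 <- mean(stats::predict(fit, newdata = nd, type = "response"))
    mu1 - mu0
  }
}

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' `icer = cost_diff / qaly_diff` when the QALY difference is non-zero. The
#' cost-effectiveness-plane quadrant is recorded alongside: `"NE"` (costlier,
#' more effective), `"SW"` (cheaper, less effective), `"dominant"` (cheaper
#' and more effective) or `"dominated"` (costlier and less effective). A zero
#' QALY difference leaves the ICER undefined (`NA`) with a classed warning;
#' report net monetary benefit instead in that case.
#'
#' @param cost_diff Incremental cost in GBP (treatment minus control).
#' @param qaly_diff Incremental QALYs.
#' @return A one-row tibble: `cost_diff`, `qaly_diff`, `icer`, `quadrant`.
#' @examples
#' compute_icer(1346, 0.0095) # 141684 to the pound, NE quadrant
#' @export
compute_icer <- function(cost_diff, qaly_diff) {
  stopifnot(is.finite(cost_diff), is.finite(qaly_diff))
  quadrant <- dplyr::case_when(
    cost_diff < 0 & qaly_diff > 0 ~ "dominant",
    cost_diff > 0 & qaly_diff < 0 ~ "dominated",
    cost_diff >= 0 & qaly_diff >= 0 ~ "NE",
    TRUE ~ "SW"
  )
  if (qaly_diff == 0) {
    rlang::warn("QALY difference is zero: ICER undefined, report net benefit",
                class = "ptsdcea_undefined_icer")
    icer <- NA_real_
  } else {
    icer <- cost_diff / qaly_diff
  }
  tibble::tibble(cost_diff = cost_diff, qaly_diff = qaly_diff,
                 icer = icer, quadrant = quadrant)
}

#' Trial-horizon cost-utility analysis
#'
#' Runs the full trial-based incremental analysis: build the per-patient
#' analysis table, impute missing follow-up data by conditional regression
#' (or restrict to complete cases), compute per-arm mean costs and QALYs,
#' covariate-adjusted differences and the ICER.
#'
#' @inheritParams trial_analysis_table
#' @param analysis `"imputed"` (default) or `"complete_case"`.
#' @param family Adjustment model family, see [adjust_difference()].
#' @param seed Seed forwarded to [impute_missing()].
#' @return An object of class `cua_result`: a list with `arms` (per-arm mean
#'   cost/QALY tibble), `icer` (from [compute_icer()]), `analysis_set` and
#'   the completed analysis `table`.
#' @export
trial_cua <- function(records, unit_costs = default_unit_costs(),
                      analysis = c("imputed", "complete_case"),
                      hourly_rate = 138, exclude_index_trauma = TRUE,
                      family = "gaussian", seed = 1L,
                      window_years = trial_window_years()) {
  analysis <- match.arg(analysis)
  tbl <- trial_analysis_table(records, unit_costs, hourly_rate,
                              exclude_index_trauma,
                              window_years = window_years)
  tbl <- if (analysis == "imputed") {
    impute_missing(tbl, seed = seed, window_years = window_years)
  } else {
    tbl[stats::complete.cases(tbl[c("cost_followup", "qaly")]), ]
  }
  arms <- tbl |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_cost = mean(.data$cost_followup),
                     sd_cost = stats::sd(.data$cost_followup),
                     mean_qaly = mean(.data$qaly),
                     sd_qaly = stats::sd(.data$qaly),
                     .groups = "drop")
  dc <- adjust_difference(tbl, "cost", family = family)
  de <- adjust_difference(tbl, "qaly")
  structure(
    list(arms = arms, icer = compute_icer(dc, de),
         analysis_set = analysis, table = tbl),
    class = "cua_result")
}

#' @export
print.cua_result <- function(x, ...) {
  cat("Trial cost-utility analysis (", x$analysis_set, " data)\n", sep = "")
  print(x$arms)
  cat("\nAdjusted incremental cost: ", round_gbp(x$icer$cost_diff),
      " GBP; incremental QALYs: ", signif(x$icer$qaly_diff, 3), "\n",
      sep = "")
  if (is.na(x$icer$icer)) {
    cat("ICER undefined (zero QALY difference)\n")
  } else {
    cat("ICER: ", round_gbp(x$icer$icer), " GBP/QALY (quadrant ",
        x$icer$quadrant, ")\n", sep = "")
  }
  invisible(x)
}
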