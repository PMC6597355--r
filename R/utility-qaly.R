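#' SDQ-to-CHU-9D mapping coefficients
#'
#' Coefficients of the published linear crosswalk from the five parent-rated
#' Strengths and Difficulties Questionnaire (SDQ) subscale scores to a
#' Child Health Utility 9D (CHU-9D) utility weight:
#'
#' utility = 0.88 - 0.019 emotion - 0.009 conduct - 0.001 hyper
#'           - 0.008 peer + 0.005 prosocial
#'
#' Each subscale is scored 0-10. Over that domain the mapped utility spans
#' exactly \[0.51, 0.93\].
#'
#' @param intercept,emotion,conduct,hyper,peer,prosocial Numeric coefficients
#'   overriding the published defaults.
#' @return A named numeric vector of class `chu9d_coefficients`.
#' @examples
#' chu9d_coefficients()
#' @export
chu9d_coefficients <- function(intercept = 0.88, emotion = -0.019,
                               conduct = -0.009, hyper = -0.001,
                               peer = -0.008, prosocial = 0.005) {
  coeffs <- c(intercept = intercept, emotion = emotion, conduct = conduct,
              hyper = hyper, peer = peer, prosocial = prosocial)
  stopifnot(is.numeric(coeffs), all(is.finite(coeffs)))
  structure(coeffs, class = c("chu9d_coefficients", "numeric"))
}

check_sdq <- function(x, name) {
  bad <- !is.na(x) & (x < 0 | x > 10)
  if (any(bad)) {
    rlang::abort(
      sprintf("SDQ subscale `%s` outside [0, 10]: %s",
              name, paste(utils::head(x[bad], 3), collapse = ", ")),
      class = "ptsdcea_domain_error"
    )
  }
  invisible(x)
}

#' Map SDQ subscale scores to a CHU-9D utility weight
#'
#' Applies the linear crosswalk to (vectors of) subscale scores. Inputs must
#' lie in \[0, 10\]; values outside the domain are rejected, not clamped,
#' since within the domain the mapping cannot leave \[0.51, 0.93\] under the
#' default coefficients. `NA` scores propagate to `NA` utilities.
#'
#' @param emotion,conduct,hyper,peer,prosocial Subscale scores in \[0, 10\]
#'   (recycled to a common length).
#' @param coeffs A [chu9d_coefficients()] vector.
#' @return A numeric vector of utility weights.
#' @examples
#' sdq_to_utility(0, 0, 0, 0, 0)   # 0.88, the intercept
#' sdq_to_utility(10, 10, 10, 10, 0) # 0.51, the floor of the mapping
#' @export
sdq_to_utility <- function(emotion, conduct, hyper, peer, prosocial,
                           coeffs = chu9d_coefficients()) {
  scores <- list(emotion = emotion, conduct = conduct, hyper = hyper,
                 peer = peer, prosocial = prosocial)
  purrr::iwalk(scores, check_sdq)
  coeffs[["intercept"]] +
    coeffs[["emotion"]] * emotion +
    coeffs[["conduct"]] * conduct +
    coeffs[["hyper"]] * hyper +
    coeffs[["peer"]] * peer +
    coeffs[["prosocial"]] * prosocial
}

#' Add mapped utilities to a patient-record table
#'
#' Computes `utility_baseline` and `utility_followup` columns from the
#' `sdq_*_baseline` / `sdq_*_followup` columns produced by
#' [generate_cohort()].
#'
#' @param records A patient-record tibble.
#' @param coeffs A [chu9d_coefficients()] vector.
#' @return `records` with two utility columns appended.
#' @export
add_utilities <- function(records, coeffs = chu9d_coefficients()) {
  dplyr::mutate(
    records,
    utility_baseline = sdq_to_utility(
      .data$sdq_emotion_baseline, .data$sdq_conduct_baseline,
      .data$sdq_hyper_baseline, .data$sdq_peer_baseline,
      .data$sdq_prosocial_baseline, coeffs = coeffs),
    utility_followup = sdq_to_utility(
      .data$sdq_emotion_followup, .data$sdq_conduct_followup,
      .data$sdq_hyper_followup, .data$sdq_peer_followup,
      .data$sdq_prosocial_followup, coeffs = coeffs)
  )
}

#' Accrue QALYs between two utility measurements
#'
#' Quality-adjusted life years are survival time weighted by a utility: a
#' constant utility of 0.5 held for two years yields one QALY. Between two
#' measurement points the utility is interpolated linearly, so the accrual is
#' the trapezoid `duration * (utility_start + utility_end) / 2`.
#'
#' @param utility_start,utility_end Utility weights at the two time points
#'   (vectorised).
#' @param duration Elapsed time in years; must be positive.
#' @return QALYs accrued over the interval.
#' @examples
#' accrue_qalys(0.5, 0.5, 2)        # 1 QALY
#' accrue_qalys(0.8, 1.0, 0.5)      # 0.45
#' @export
accrue_qalys <- function(utility_start, utility_end, duration) {
  if (any(!is.finite(duration)) || any(duration <= 0)) {
    rlang::abort("`duration` must be positive and finite.",
                 class = "ptsdcea_domain_error")
  }
  duration * (utility_start + utility_end) / 2
}

#' Trial QALY window in years
#'
#' The trial follow-up is at 11 weeks; QALYs over the trial horizon are
#' accrued over 11/52.18 years (52.18 weeks per average year).
#'
#' @return Length of the trial window in years.
#' @export
trial_window_years <- function() 11 / 52.18
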