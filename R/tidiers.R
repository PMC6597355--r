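#' Tidy a cost-utility result
#'
#' @param x A `cua_result`.
#' @param ... Unused.
#' @return A tibble with one row per arm-level and incremental quantity.
#' @method tidy cua_result
#' @export
tidy.cua_result <- function(x, ...) {
  arm_cols <- intersect(c("mean_cost", "mean_qaly", "cost", "qaly"),
                        names(x$arms))
  arms <- tidyr::pivot_longer(x$arms, dplyr::all_of(arm_cols),
                              names_to = "quantity", values_to = "estimate")
  arms <- dplyr::transmute(
    arms, term = paste(.data$quantity, .data$arm, sep = "_"),
    estimate = .data$estimate)
  incr <- tibble::tibble(
    term = c("cost_diff", "qaly_diff", "icer"),
    estimate = c(x$icer$cost_diff, x$icer$qaly_diff, x$icer$icer))
  dplyr::bind_rows(arms, incr)
}

#' Summarise a cost-utility result in one row
#'
#' @param x A `cua_result`.
#' @param ... Unused.
#' @return A one-row tibble: `cost_diff`, `qaly_diff`, `icer`, `quadrant`,
#'   `analysis_set`.
#' @method glance cua_result
#' @export
glance.cua_result <- function(x, ...) {
  dplyr::mutate(x$icer, analysis_set = x$analysis_set)
}

#' Tidy a Markov trajectory
#'
#' @param x A `markov_trajectory`.
#' @param ... Unused.
#' @return The per-cycle tibble with the arm attached as a column.
#' @method tidy markov_trajectory
#' @export
tidy.markov_trajectory <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x), arm = attr(x, "arm"),
                .before = 1)
}

#' Summarise a PSA draw set
#'
#' @param x A `psa_draws` tibble.
#' @param ... Unused.
#' @return A one-row tibble with mean deltas at the horizon and quadrant
#'   fractions.
#' @method glance psa_draws
#' @export
glance.psa_draws <- function(x, ...) {
  y <- attr(x, "horizon_years") %||% 3
  tibble::tibble(
    n_draws = nrow(x),
    mean_delta_cost = mean(x[[paste0("delta_cost_y", y)]]),
    mean_delta_qaly = mean(x[[paste0("delta_qaly_y", y)]]),
    frac_ne = mean(x$quadrant == "NE"),
    frac_dominant = mean(x$quadrant == "dominant"),
    frac_dominated = mean(x$quadrant == "dominated"),
    frac_sw = mean(x$quadrant == "SW"))
}
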