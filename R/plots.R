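#' Cost-effectiveness plane of PSA draws
#'
#' Scatter of incremental QALYs against incremental costs at a year
#' boundary, with the origin axes drawn and, optionally, a
#' willingness-to-pay line.
#'
#' @param draws A [sample_psa()] tibble.
#' @param year Year boundary (default the draw horizon).
#' @param wtp Optional willingness-to-pay threshold in GBP/QALY drawn as a
#'   line through the origin.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(draws, year = NULL, wtp = NULL) {
  if (is.null(year)) year <- attr(draws, "horizon_years") %||% 3
  dat <- tibble::tibble(
    delta_qaly = draws[[paste0("delta_qaly_y", year)]],
    delta_cost = draws[[paste0("delta_cost_y", year)]])
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$delta_qaly,
                                         .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.25, size = 0.8) +
    ggplot2::labs(x = "Incremental QALYs",
                  y = "Incremental cost (GBP)",
                  title = sprintf("Cost-effectiveness plane, year %d", year))
  if (!is.null(wtp))
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0,
                                  linetype = "dashed")
  p
}

#' @rdname plot_ce_plane
#' @param object A `psa_draws` tibble (for `autoplot`).
#' @param ... Passed to `plot_ce_plane()`.
#' @method autoplot psa_draws
#' @export
autoplot.psa_draws <- function(object, ...) plot_ce_plane(object, ...)

#' Plot a cost-effectiveness acceptability curve
#'
#' @param curve A [ceac()] tibble.
#' @param anchors Thresholds to mark with vertical reference lines
#'   (default the 20,000 and 30,000 GBP/QALY decision anchors).
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve, anchors = c(20000, 30000)) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$threshold,
                                      .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = anchors, linetype = "dotted") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (GBP/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve")
}

#' @rdname plot_ceac
#' @param object A `ceac_curve` tibble (for `autoplot`).
#' @param ... Passed to `plot_ceac()`.
#' @method autoplot ceac_curve
#' @export
autoplot.ceac_curve <- function(object, ...) plot_ceac(object, ...)

#' Plot state occupancy over the model horizon
#'
#' @param trajectory A [run_cohort_model()] trajectory.
#' @return A ggplot object.
#' @export
plot_occupancy <- function(trajectory) {
  dat <- tidyr::pivot_longer(tibble::as_tibble(trajectory),
                             c("occupancy_ptsd", "occupancy_free"),
                             names_to = "state", names_prefix = "occupancy_",
                             values_to = "occupancy")
  ggplot2::ggplot(dat, ggplot2::aes(.data$cycle, .data$occupancy,
                                    colour = .data$state)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Cycle (3 months)", y = "State occupancy",
                  colour = "State")
}
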