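#' Packaged unit-cost table
#'
#' A synthetic illustrative unit-cost table (2014 GBP price year) for the
#' resource-use categories produced by [generate_cohort()]. Magnitudes are
#' loosely modelled on published UK child mental-health unit costs; the
#' trial's actual per-category unit costs are not public, so this fixture is
#' illustrative, not canonical. Categories flagged `index_trauma` (emergency
#' department, ambulance) can be excluded from costing, matching the
#' evaluation's exclusion of care attributable to the index trauma itself.
#'
#' @param path Optional path to an alternative CSV with columns `category`,
#'   `setting` (`hospital`/`community`), `unit`, `cost_gbp`, `index_trauma`.
#' @param price_year Price year recorded on the table.
#' @return A tibble of class `unit_cost_table` with a `price_year` attribute.
#' @export
default_unit_costs <- function(path = NULL, price_year = 2014) {
  if (is.null(path)) {
    path <- system.file("extdata", "unit_costs.csv", package = "ptsdcea",
                        mustWork = TRUE)
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           category = readr::col_character(),
                           setting = readr::col_character(),
                           unit = readr::col_character(),
                           cost_gbp = readr::col_double(),
                           index_trauma = readr::col_logical()))
  if (any(tbl$cost_gbp < 0))
    rlang::abort("unit costs must be non-negative",
                 class = "ptsdcea_costing_error")
  structure(tbl, price_year = price_year,
            class = c("unit_cost_table", class(tbl)))
}

#' Cost the intervention from therapist contact time
#'
#' The intervention cost is contact time multiplied by the hourly unit cost
#' of a clinical psychologist (default 138 GBP/hour, 2014 prices, including
#' employer on-costs, overheads and non-contact time). Arithmetic is done on
#' the unrounded value; `round_gbp()` gives the whole-pound reported figure
#' (636.25 minutes at 138/hour is 1463.375, reported 1463).
#'
#' @param contact_minutes Contact time in minutes (vectorised).
#' @param hourly_rate Hourly rate in GBP.
#' @return Unrounded cost in GBP.
#' @examples
#' round_gbp(cost_intervention(636.25)) # 1463
#' @export
cost_intervention <- function(contact_minutes, hourly_rate = 138) {
  if (any(contact_minutes < 0, na.rm = TRUE) || any(hourly_rate < 0))
    rlang::abort("contact minutes and hourly rate must be non-negative",
                 class = "ptsdcea_costing_error")
  contact_minutes / 60 * hourly_rate
}

#' Round a GBP amount to the whole pound for reporting
#' @param x Amount in GBP.
#' @return `x` rounded to 0 decimal places.
#' @export
round_gbp <- function(x) round(x, 0)

#' Price per-patient resource use
#'
#' Multiplies each `res_<category>_<period>` count by its unit cost and
#' aggregates into hospital, community, intervention and total costs per
#' patient and period. Index-trauma-flagged categories are excluded when
#' `exclude_index_trauma` is `TRUE`. Follow-up costs are `NA` for records
#' whose follow-up block is missing; the intervention cost (from contact
#' minutes, treatment arm only) is attached to follow-up.
#'
#' @param records A patient-record tibble.
#' @param unit_costs A [default_unit_costs()] table.
#' @param hourly_rate Therapist hourly rate in GBP (default 138).
#' @param exclude_index_trauma Drop index-trauma categories (default `TRUE`).
#' @return A tibble: `id`, `arm`, then per period `hospital_costs_*`,
#'   `community_costs_*`, plus `intervention_cost`, `total_cost_baseline`
#'   and `total_cost_followup` (GBP, unrounded).
#' @export
aggregate_costs <- function(records, unit_costs = default_unit_costs(),
                            hourly_rate = 138, exclude_index_trauma = TRUE) {
  res_cols <- grep("^res_", names(records), value = TRUE)
  cats <- unique(sub("_(baseline|followup)$", "", sub("^res_", "", res_cols)))
  unknown <- setdiff(cats, unit_costs$category)
  if (length(unknown) > 0)
    rlang::abort(sprintf("no unit cost for resource category: %s",
                         paste(unknown, collapse = ", ")),
                 class = "ptsdcea_costing_error")

  priced <- unit_costs
  if (exclude_index_trauma)
    priced$cost_gbp[priced$index_trauma] <- 0

  period_cost <- function(period, setting) {
    use <- priced[priced$setting == setting, ]
    cols <- paste0("res_", use$category, "_", period)
    keep <- cols %in% names(records)
    m <- as.matrix(records[cols[keep]])
    as.numeric(m %*% use$cost_gbp[keep])
  }

  tibble::tibble(
    id = records$id,
    arm = records$arm,
    hospital_costs_baseline = period_cost("baseline", "hospital"),
    community_costs_baseline = period_cost("baseline", "community"),
    hospital_costs_followup = period_cost("followup", "hospital"),
    community_costs_followup = period_cost("followup", "community"),
    intervention_cost = cost_intervention(records$contact_minutes,
                                          hourly_rate)
  ) |>
    dplyr::mutate(
      total_cost_baseline = .data$hospital_costs_baseline +
        .data$community_costs_baseline,
      total_cost_followup = .data$hospital_costs_followup +
        .data$community_costs_followup + .data$intervention_cost
    )
}
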