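#' Build a per-capita state-month outcome panel
#'
#' Aggregates injurious incident records into a rectangular state-by-month
#' panel of incident counts and rates per 1,000,000 residents for one outcome
#' category. Incidents (events), not victims, are counted. State-months with
#' no matching incidents are zero-filled, so the panel always has
#' `length(states) * length(months)` cells.
#'
#' Population denominators are annual: each calendar month uses its year's
#' resident count, so `rate = count * 1e6 / population(state, year)`.
#'
#' @param records Incident record tibble, already passed through
#'   [filter_injurious()].
#' @param pop Population table: a data frame with columns `state`, `year`,
#'   `population` covering every state and year in the window.
#' @param category One of [outcome_categories()].
#' @param window Length-2 month window (`"YYYY-MM"` or Dates); defaults to
#'   2014-01 through 2021-12.
#' @param states Panel units. Defaults to all states in `pop`.
#' @param strict Passed to the intent classifier; see [classify_incident()].
#' @return A `state_month_panel`: a tibble with columns `state`, `month`
#'   (Date, first of month), `count`, `population`, and `rate` (incidents per
#'   1,000,000 residents per month), carrying the category and window as
#'   attributes.
#' @examples
#' recs <- tibble::tibble(
#'   state = "VT", date = as.Date("2016-03-10"), n_injured = 1L,
#'   n_killed = 0L, intent = "assault", mass_shooting = FALSE
#' )
#' pop <- tibble::tibble(state = "VT", year = 2016, population = 625000)
#' aggregate_rates(recs, pop, window = c("2016-01", "2016-06"))
#' @export
aggregate_rates <- function(records, pop, category = "all_violence",
                            window = default_window(), states = NULL,
                            strict = FALSE) {
  category <- match.arg(category, outcome_categories())
  check_window_end(window)
  months <- month_seq(window[[1]], window[[2]])
  states <- states %||% sort(unique(pop$state))

  records <- dplyr::mutate(records, month = as_month(.data$date))
  records <- dplyr::filter(
    records,
    .data$month >= months[[1]], .data$month <= months[[length(months)]]
  )

  missing_states <- setdiff(unique(records$state), pop$state)
  if (length(missing_states) > 0) {
    abort(paste0(
      "State(s) in incident records absent from the population table: ",
      paste(missing_states, collapse = ", ")
    ))
  }

  if (nrow(records) > 0) {
    keep <- category_flags(records, strict = strict)[, category]
    matched <- records[keep, c("state", "month")]
  } else {
    matched <- tibble::tibble(state = character(), month = as.Date(character()))
  }

  grid <- tidyr::expand_grid(state = states, month = months)
  counts <- dplyr::count(matched, .data$state, .data$month, name = "count")
  panel <- dplyr::left_join(grid, counts, by = c("state", "month"))
  panel$count <- dplyr::coalesce(panel$count, 0L)

  panel$year <- lubridate::year(panel$month)
  panel <- dplyr::left_join(
    panel,
    dplyr::select(pop, "state", "year", "population"),
    by = c("state", "year")
  )
  if (anyNA(panel$population)) {
    bad <- dplyr::distinct(panel[is.na(panel$population), ], .data$state, .data$year)
    abort(paste0(
      "Population table is missing ",
      paste(sprintf("%s %d", bad$state, bad$year), collapse = ", ")
    ))
  }
  panel$rate <- panel$count * 1e6 / panel$population
  panel$year <- NULL

  new_state_month_panel(panel, category = category, window = window)
}

new_state_month_panel <- function(data, category, window) {
  out <- tibble::new_tibble(
    data,
    category = category,
    window = format_month(as_month(unlist(window))),
    class = "state_month_panel"
  )
  out
}

#' Construct a panel directly from state-month rates
#'
#' Wraps an already-aggregated long table (for instance the simulator's
#' ground-truth rates) in the panel class used by the fitting functions.
#'
#' @param data Tibble with columns `state`, `month`, `rate`, and optionally
#'   `count` and `population`.
#' @param category Outcome category label for the panel.
#' @return A `state_month_panel`.
#' @export
as_state_month_panel <- function(data, category = "all_violence") {
  data <- dplyr::arrange(
    dplyr::mutate(data, month = as_month(.data$month)),
    .data$state, .data$month
  )
  window <- range(data$month)
  new_state_month_panel(data, category = category, window = window)
}

#' Panel as a unit-by-month matrix
#'
#' @param panel A `state_month_panel`.
#' @param value Column to spread, `"rate"` (default) or `"count"`.
#' @return A numeric matrix, states in rows (ordered as in the panel), months
#'   in `"YYYY-MM"` columns.
#' @export
panel_matrix <- function(panel, value = c("rate", "count")) {
  if (is.matrix(panel)) {
    # already a unit-by-month matrix (internal fast path for repeated fits)
    return(panel)
  }
  value <- match.arg(value)
  wide <- tidyr::pivot_wider(
    dplyr::select(panel, "state", "month", dplyr::all_of(value)),
    names_from = "month", values_from = dplyr::all_of(value)
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$state
  colnames(m) <- format_month(as.Date(colnames(m)))
  if (anyNA(m)) {
    abort("Panel has missing cells; it is not rectangular.")
  }
  m
}

#' Export a panel to CSV
#'
#' Writes the panel in long form (`state, month, category, count, rate`) or
#' wide form (states by months, rate values).
#'
#' @param panel A `state_month_panel`.
#' @param path Output file path.
#' @param shape `"long"` (default) or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path, shape = c("long", "wide")) {
  shape <- match.arg(shape)
  if (shape == "long") {
    out <- dplyr::mutate(
      dplyr::select(panel, "state", "month", dplyr::any_of(c("count", "rate"))),
      month = format_month(.data$month),
      category = attr(panel, "category") %||% "all_violence",
      .after = "month"
    )
    readr::write_csv(out, path)
  } else {
    m <- panel_matrix(panel, "rate")
    out <- tibble::as_tibble(m, rownames = "state")
    readr::write_csv(out, path)
  }
  invisible(path)
}

#' @export
print.state_month_panel <- function(x, ...) {
  cat(sprintf(
    "<state_month_panel> %s | %d states x %d months (%s..%s)\n",
    attr(x, "category") %||% "?", dplyr::n_distinct(x$state),
    dplyr::n_distinct(x$month), attr(x, "window")[1], attr(x, "window")[2]
  ))
  NextMethod()
}
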