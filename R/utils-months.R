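#' Month handling utilities
#'
#' Panels are indexed by calendar month. Internally a month is a `Date` fixed
#' to the first day of the month; externally months read and write as
#' `"YYYY-MM"` strings.
#'
#' @param x A `Date` vector, or a character vector in `"YYYY-MM"` or
#'   `"YYYY-MM-DD"` form.
#' @return `as_month()` returns a `Date` vector floored to the first of the
#'   month; `format_month()` returns a `"YYYY-MM"` character vector;
#'   `month_seq()` returns a contiguous `Date` sequence by month.
#' @examples
#' as_month("2016-12")
#' format_month(as.Date("2016-12-08"))
#' month_seq("2014-01", "2014-04")
#' @export
as_month <- function(x) {
  if (inherits(x, "Date")) {
    return(lubridate::floor_date(x, "month"))
  }
  x <- as.character(x)
  x <- ifelse(grepl("^\\d{4}-\\d{2}$", x), paste0(x, "-01"), x)
  out <- as.Date(x)
  lubridate::floor_date(out, "month")
}

#' @rdname as_month
#' @export
format_month <- function(x) {
  format(as_month(x), "%Y-%m")
}

#' @param from,to Window endpoints, in any form `as_month()` accepts.
#' @rdname as_month
#' @export
month_seq <- function(from, to) {
  from <- as_month(from)
  to <- as_month(to)
  if (length(from) != 1L || length(to) != 1L || is.na(from) || is.na(to)) {
    abort("`from` and `to` must each be a single parseable month.")
  }
  if (from > to) {
    abort("Empty month window: `from` is after `to`.")
  }
  seq(from, to, by = "month")
}

# Default study window: 2022+ incident sources changed how self-directed
# violence is captured, so the default panel ends at 2021-12.
default_window <- function() {
  c("2014-01", "2021-12")
}

check_window_end <- function(window) {
  if (as_month(window[[2]]) > as_month("2021-12")) {
    warn(paste0(
      "Window extends past 2021-12; self-harm incident capture changed in ",
      "2022 and later months may not be comparable."
    ))
  }
  invisible(window)
}
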