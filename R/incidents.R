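#' Outcome categories
#'
#' The seven outcome stratifications used throughout the pipeline. The three
#' base intent labels map to four elementary categories by fatality
#' (`nonfatal_assault`, `homicide`, `nonfatal_self_harm`, `suicide`); the
#' composites combine them (`other_directed` = assault + homicide,
#' `self_directed` = self-harm + suicide); `all_violence` contains every
#' injurious incident regardless of intent.
#'
#' @return Character vector of category names.
#' @export
outcome_categories <- function() {
  c(
    "all_violence", "nonfatal_assault", "homicide", "other_directed",
    "nonfatal_self_harm", "suicide", "self_directed"
  )
}

incident_intents <- function() {
  c("assault", "self_harm", "unintentional", "undetermined")
}

incident_columns <- function() {
  c("state", "date", "n_injured", "n_killed", "intent", "mass_shooting")
}

#' Read firearm-violence incident records
#'
#' Reads an incident-level CSV (one row per firearm-violence event) and
#' validates it into a typed record table. Rows with unparseable dates or
#' negative victim counts are dropped, and each dropped row is reported with
#' its row number and offending field.
#'
#' @param path Path to a CSV with columns `state`, `date` (ISO-8601),
#'   `n_injured`, `n_killed`, `intent`, and optionally `mass_shooting`.
#' @param schema Optional named character vector mapping the canonical column
#'   names to the names used in the file, e.g.
#'   `c(n_injured = "injured", n_killed = "killed")`.
#' @return A tibble of incident records. Rejected rows (if any) are attached
#'   as a tibble in the `"rejected"` attribute, with columns `row` and
#'   `reason`, and reported via a warning.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write.csv(
#'   data.frame(
#'     state = "RI", date = "2018-06-15", n_injured = 1L, n_killed = 0L,
#'     intent = "assault", mass_shooting = FALSE
#'   ),
#'   path,
#'   row.names = FALSE
#' )
#' read_incidents(path)
#' @export
read_incidents <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Incident file not found: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (schema[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == schema[[canon]]] <- canon
      }
    }
  }
  required <- setdiff(incident_columns(), "mass_shooting")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Incident file is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!"mass_shooting" %in% names(raw)) {
    raw$mass_shooting <- "FALSE"
  }

  date <- as.Date(raw$date, format = "%Y-%m-%d")
  n_injured <- suppressWarnings(as.integer(raw$n_injured))
  n_killed <- suppressWarnings(as.integer(raw$n_killed))

  reasons <- rep(NA_character_, nrow(raw))
  reasons[is.na(date)] <- "unparseable date"
  reasons[is.na(n_injured) | n_injured < 0] <- "invalid n_injured (negative or non-integer)"
  reasons[is.na(n_killed) | n_killed < 0] <- "invalid n_killed (negative or non-integer)"
  bad <- !is.na(reasons)

  rejected <- tibble::tibble(row = which(bad), reason = reasons[bad])
  if (nrow(rejected) == nrow(raw)) {
    abort("All rows in the incident file were rejected; check the schema.")
  }
  if (nrow(rejected) > 0) {
    warn(paste0(
      nrow(rejected), " incident row(s) rejected: ",
      paste(sprintf("row %d (%s)", rejected$row, rejected$reason), collapse = "; ")
    ))
  }

  out <- tibble::tibble(
    state = as.character(raw$state)[!bad],
    date = date[!bad],
    n_injured = n_injured[!bad],
    n_killed = n_killed[!bad],
    intent = as.character(raw$intent)[!bad],
    mass_shooting = as.logical(raw$mass_shooting)[!bad]
  )
  attr(out, "rejected") <- rejected
  out
}

#' Keep only injurious incidents
#'
#' Retains the incidents that resulted in at least one person injured or
#' killed. Events with no casualties (warning shots, gun-involved robberies
#' without injury, firearm recoveries) do not enter the outcome and are
#' dropped. Input order is preserved and the operation is idempotent.
#'
#' @param records Incident record tibble (see [read_incidents()]).
#' @return The subset of `records` with `n_injured + n_killed >= 1`.
#' @export
filter_injurious <- function(records) {
  dplyr::filter(records, .data$n_injured + .data$n_killed >= 1)
}

#' Classify incidents into outcome categories
#'
#' Maps each injurious incident to the set of outcome categories it counts
#' toward. Every incident counts toward `all_violence`. Assault incidents
#' count toward `homicide` when at least one person was killed and toward
#' `nonfatal_assault` otherwise; self-harm incidents map to `suicide` /
#' `nonfatal_self_harm` the same way. An incident with both a death and a
#' nonfatal injury maps to the fatal category only, so the elementary
#' categories stay additive within each composite. Unintentional and
#' undetermined incidents count toward `all_violence` only.
#'
#' @param records Incident record tibble.
#' @param strict If `TRUE`, an unknown intent label is an error; if `FALSE`
#'   (default) it is treated as `undetermined`.
#' @return A list of character vectors, one per record: the categories the
#'   record counts toward.
#' @examples
#' recs <- tibble::tibble(
#'   state = "MA", date = as.Date("2019-01-15"),
#'   n_injured = c(1L, 0L, 1L), n_killed = c(0L, 1L, 0L),
#'   intent = c("assault", "self_harm", "unintentional"),
#'   mass_shooting = FALSE
#' )
#' classify_incident(recs)
#' @export
classify_incident <- function(records, strict = FALSE) {
  flags <- category_flags(records, strict = strict)
  apply(flags, 1L, function(row) colnames(flags)[row], simplify = FALSE)
}

# Logical record-by-category membership matrix; the workhorse behind both
# classify_incident() and aggregate_rates().
category_flags <- function(records, strict = FALSE) {
  intent <- records$intent
  unknown <- !intent %in% incident_intents()
  if (any(unknown)) {
    if (strict) {
      abort(paste0(
        "Unknown intent label(s): ",
        paste(unique(intent[unknown]), collapse = ", ")
      ))
    }
    intent[unknown] <- "undetermined"
  }
  fatal <- records$n_killed >= 1

  homicide <- intent == "assault" & fatal
  nonfatal_assault <- intent == "assault" & !fatal
  suicide <- intent == "self_harm" & fatal
  nonfatal_self_harm <- intent == "self_harm" & !fatal

  cbind(
    all_violence = rep(TRUE, nrow(records)),
    nonfatal_assault = nonfatal_assault,
    homicide = homicide,
    other_directed = nonfatal_assault | homicide,
    nonfatal_self_harm = nonfatal_self_harm,
    suicide = suicide,
    self_directed = nonfatal_self_harm | suicide
  )
}
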