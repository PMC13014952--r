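#' Configure a full study run
#'
#' Collects every input and option the end-to-end pipeline needs. Each data
#' argument may be a data frame or a path to a CSV in the package's
#' dialects.
#'
#' @param incidents Incident records (tibble or CSV path; see
#'   [read_incidents()]).
#' @param populations Population table (`state`, `year`, `population`).
#' @param policy_catalog Policy catalog (see [read_policy_catalog()]).
#' @param petitions Petition series (`state`, `month`, `petitions`).
#' @param covariates Optional covariate table for the predictor spec.
#' @param window Panel month window.
#' @param spec A [predictor_spec()].
#' @param categories Outcome categories to analyze; the first is used for
#'   the fit gate and cohort-level significance (default: all seven).
#' @param v_method,n_starts Synthetic-control importance optimization
#'   options (see [scm_fit()]).
#' @param ci_method Yearly-effect interval method (see [yearly_effects()]).
#' @param tau1,tau2 Fit-gate thresholds (see [fit_gate()]).
#' @param alpha Petition-test significance level.
#' @param filter_ratio Optional placebo pre-fit filter (see
#'   [rank_p_value()]).
#' @param seed Integer seed governing every stochastic step.
#' @return A `study_config` list.
#' @export
study_config <- function(incidents, populations, policy_catalog, petitions,
                         covariates = NULL, window = default_window(),
                         spec = predictor_spec(), categories = outcome_categories(),
                         v_method = "nested", n_starts = 10,
                         ci_method = "monthly", tau1 = 0.10, tau2 = 2.0,
                         alpha = 0.05, filter_ratio = NULL, seed = 1) {
  categories <- match.arg(categories, outcome_categories(), several.ok = TRUE)
  structure(
    list(
      incidents = incidents, populations = populations,
      policy_catalog = policy_catalog, petitions = petitions,
      covariates = covariates, window = window, spec = spec,
      categories = categories, v_method = v_method, n_starts = n_starts,
      ci_method = ci_method, tau1 = tau1, tau2 = tau2, alpha = alpha,
      filter_ratio = filter_ratio, seed = seed
    ),
    class = "study_config"
  )
}

load_table <- function(x, reader = readr::read_csv) {
  if (is.character(x) && length(x) == 1) {
    reader(x, show_col_types = FALSE)
  } else {
    tibble::as_tibble(x)
  }
}

#' Run the full study pipeline
#'
#' Orchestrates cohort selection, per-state synthetic-control fits, placebo
#' inference, fit gating, and intent-stratified re-analysis from one
#' configuration. Every treated state is analyzed independently with its own
#' treatment month; each outcome category is a complete re-analysis (its own
#' panel, fits, and placebo ensemble), not a decomposition of another
#' category's estimate. States failing the cohort filters carry status
#' `"excluded"`; states failing the pre-period fit gate on the primary
#' category carry `"uninterpretable"` and no effect estimates; the rest are
#' `"estimated"`.
#'
#' @param config A [study_config()].
#' @return A `study_report`: `cohort` (the cohort decision table), `status`
#'   (per treated state), `inference` (per state and category: RMSPE ratio,
#'   rank, p-value), `effects` (per state, category, and implementation
#'   year), `gates`, `descriptives` (state-year petition and incident
#'   trends), `ensembles` (the fitted objects, primary category), and
#'   `provenance`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  incidents <- if (is.character(config$incidents)) {
    read_incidents(config$incidents)
  } else {
    tibble::as_tibble(config$incidents)
  }
  populations <- load_table(config$populations)
  catalog <- if (is.character(config$policy_catalog)) {
    read_policy_catalog(config$policy_catalog)
  } else {
    tibble::as_tibble(config$policy_catalog)
  }
  petitions <- load_table(config$petitions)
  petitions$month <- as_month(petitions$month)
  covariates <- if (is.null(config$covariates)) NULL else load_table(config$covariates)

  cohort <- select_cohort(catalog, petitions, window = config$window,
                          alpha = config$alpha)
  treated_states <- cohort$state[cohort$role == "treated"]
  donors <- sort(cohort$state[cohort$role == "donor"])

  records <- filter_injurious(incidents)
  units <- c(treated_states, donors)
  panels <- purrr::map(setNames(config$categories, config$categories), function(cat) {
    aggregate_rates(records, populations, category = cat,
                    window = config$window, states = units)
  })
  primary <- config$categories[[1]]

  eff_dates <- setNames(cohort$effective_date, cohort$state)

  status <- list()
  inference_rows <- list()
  effect_rows <- list()
  gate_rows <- list()
  ensembles <- list()

  for (st in treated_states) {
    tm <- as_month(eff_dates[[st]])
    res <- tryCatch({
      ens <- run_placebos(
        panels[[primary]], st, donors, tm,
        covariates = covariates, spec = config$spec,
        v_method = config$v_method, n_starts = config$n_starts,
        seed = child_seed(config$seed, match(st, treated_states))
      )
      gate <- fit_gate(ens$treated_fit, ens, tau1 = config$tau1, tau2 = config$tau2)
      list(ens = ens, gate = gate)
    }, error = function(e) e)

    if (inherits(res, "error")) {
      warn(paste0("Fit quarantined for ", st, ": ", conditionMessage(res)))
      status[[st]] <- "uninterpretable"
      gate_rows[[st]] <- tibble::tibble(
        state = st, interpretable = FALSE, relative_rmspe = NA_real_,
        placebo_multiple = NA_real_, tau1 = config$tau1, tau2 = config$tau2,
        reasons = list("fit_failure")
      )
      next
    }

    ensembles[[st]] <- res$ens
    gate_rows[[st]] <- dplyr::mutate(res$gate, state = st, .before = 1)

    if (!res$gate$interpretable) {
      status[[st]] <- "uninterpretable"
      next
    }
    status[[st]] <- "estimated"

    for (cat in config$categories) {
      ens_cat <- if (cat == primary) {
        res$ens
      } else {
        run_placebos(
          panels[[cat]], st, donors, tm,
          covariates = covariates, spec = config$spec,
          v_method = config$v_method, n_starts = config$n_starts,
          seed = child_seed(config$seed, 1000L + match(st, treated_states))
        )
      }
      pv <- rank_p_value(ens_cat, filter_ratio = config$filter_ratio)
      g <- glance(ens_cat$treated_fit)
      inference_rows[[paste(st, cat)]] <- tibble::tibble(
        state = st, category = cat,
        rmspe_pre = g$rmspe_pre, rmspe_post = g$rmspe_post,
        rmspe_ratio = g$rmspe_ratio, rank = pv$rank, n_units = pv$n_units,
        p_value = pv$p_value
      )
      eff <- yearly_effects(ens_cat$treated_fit, method = config$ci_method,
                            ensemble = ens_cat)
      effect_rows[[paste(st, cat)]] <- dplyr::mutate(
        eff, state = st, category = cat, .before = 1
      )
    }
  }

  status_tbl <- tibble::tibble(
    state = cohort$state[cohort$role != "donor"],
    status = purrr::map_chr(cohort$state[cohort$role != "donor"], function(s) {
      if (s %in% names(status)) status[[s]] else "excluded"
    })
  )

  descriptives <- build_descriptives(records, petitions, populations,
                                     treated_states, config$window)

  inference_tbl <- dplyr::bind_rows(inference_rows)
  if (nrow(inference_tbl) == 0) {
    inference_tbl <- tibble::tibble(
      state = character(), category = character(), rmspe_pre = double(),
      rmspe_post = double(), rmspe_ratio = double(), rank = integer(),
      n_units = integer(), p_value = double()
    )
  }
  gates_tbl <- dplyr::bind_rows(gate_rows)
  if (nrow(gates_tbl) == 0) {
    gates_tbl <- tibble::tibble(
      state = character(), interpretable = logical(),
      relative_rmspe = double(), placebo_multiple = double(),
      tau1 = double(), tau2 = double(), reasons = list()
    )
  }
  effects_tbl <- dplyr::bind_rows(effect_rows)
  if (nrow(effects_tbl) == 0) {
    effects_tbl <- tibble::tibble(
      state = character(), category = character(), year = double(),
      n_months = integer(), effect = double(), ci_low = double(),
      ci_high = double(), synthetic_annual = double(),
      percent_change = double()
    )
  }
  structure(
    list(
      cohort = cohort,
      status = status_tbl,
      inference = inference_tbl,
      effects = effects_tbl,
      gates = gates_tbl,
      descriptives = descriptives,
      ensembles = ensembles,
      donors = donors,
      provenance = list(
        seed = config$seed,
        categories = config$categories,
        window = as.character(config$window),
        config_hash = rlang::hash(config[setdiff(names(config), "incidents")]),
        timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
      )
    ),
    class = "study_report"
  )
}

# State-year descriptive trends for the treated cohort: petition volume and
# injurious incident counts/rates by category.
build_descriptives <- function(records, petitions, populations,
                               treated_states, window) {
  months <- month_seq(window[[1]], window[[2]])
  recs <- dplyr::filter(records, .data$state %in% treated_states)
  recs <- dplyr::mutate(recs, month = as_month(.data$date))
  recs <- dplyr::filter(recs, .data$month >= months[[1]],
                        .data$month <= months[[length(months)]])
  if (nrow(recs) > 0) {
    flags <- category_flags(recs)
    recs$year <- lubridate::year(recs$month)
    counts <- purrr::map(
      setNames(outcome_categories(), outcome_categories()),
      function(cat) {
        dplyr::count(recs[flags[, cat], ], .data$state, .data$year, name = cat)
      }
    )
    counts <- purrr::reduce(counts, dplyr::full_join, by = c("state", "year"))
  } else {
    counts <- tibble::tibble(state = character(), year = integer())
  }
  pets <- dplyr::filter(petitions, .data$state %in% treated_states)
  pets <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(pets, year = lubridate::year(as_month(.data$month))),
      .data$state, .data$year
    ),
    petitions = sum(.data$petitions), .groups = "drop"
  )
  out <- dplyr::full_join(pets, counts, by = c("state", "year"))
  out <- dplyr::left_join(out, populations, by = c("state", "year"))
  dplyr::mutate(
    out,
    dplyr::across(
      dplyr::any_of(outcome_categories()),
      ~ dplyr::coalesce(.x, 0L)
    )
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  print(dplyr::count(x$status, .data$status))
  if (nrow(x$inference) > 0) {
    cat("Primary-category inference:\n")
    prim <- x$inference[x$inference$category == x$provenance$categories[[1]], ]
    print(as.data.frame(prim[, c("state", "rmspe_ratio", "rank", "p_value")]),
          row.names = FALSE)
  }
  invisible(x)
}

#' @rdname run_study
#' @param x A `study_report`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.study_report <- function(x, ...) {
  tibble::tibble(
    n_treated = sum(x$status$status != "excluded"),
    n_excluded = sum(x$status$status == "excluded"),
    n_uninterpretable = sum(x$status$status == "uninterpretable"),
    n_estimated = sum(x$status$status == "estimated"),
    n_donors = length(x$donors),
    seed = x$provenance$seed
  )
}

#' Export a study report
#'
#' Writes the report's tables as CSVs (cohort decisions, statuses, ratio and
#' p-value table, yearly effects, fit gates, descriptive trends, and
#' per-state gap-plot data) plus a JSON manifest with run provenance.
#' Re-running the export overwrites the same files with identical content.
#'
#' @param report A `study_report`.
#' @param dir Output directory.
#' @return Named vector of the files written, invisibly.
#' @export
export_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    cohort = file.path(dir, "cohort.csv"),
    status = file.path(dir, "status.csv"),
    inference = file.path(dir, "inference.csv"),
    effects = file.path(dir, "effects.csv"),
    gates = file.path(dir, "gates.csv"),
    descriptives = file.path(dir, "descriptives.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  cohort_flat <- dplyr::mutate(
    report$cohort,
    failed_filters = purrr::map_chr(.data$failed_filters, paste, collapse = ";")
  )
  readr::write_csv(cohort_flat, paths[["cohort"]])
  readr::write_csv(report$status, paths[["status"]])
  readr::write_csv(report$inference, paths[["inference"]])
  readr::write_csv(report$effects, paths[["effects"]])
  gates_flat <- dplyr::mutate(
    report$gates,
    reasons = purrr::map_chr(.data$reasons, paste, collapse = ";")
  )
  readr::write_csv(gates_flat, paths[["gates"]])
  readr::write_csv(report$descriptives, paths[["descriptives"]])
  for (st in names(report$ensembles)) {
    gp <- write_placebo_ensemble(report$ensembles[[st]], dir, prefix = st)
    paths <- c(paths, gp)
  }
  jsonlite::write_json(report$provenance, paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
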