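#' Specify the predictor set for a synthetic-control fit
#'
#' A predictor is either a covariate aggregated over the pre-policy period or
#' a pre-period outcome summary ("lag"). The default lag convention summarizes
#' the pre-period outcome path by the means of its first, middle, and last
#' thirds, which anchors the fit to the level and shape of the pre-period
#' trajectory without using every month as a separate predictor.
#'
#' @param covariates Character vector of covariate column names (in the
#'   covariate table passed to [build_predictors()]).
#' @param cov_rule Aggregation rule over the pre-period for covariates:
#'   `"mean"` (default) or `"last"`; either a single rule or a named vector
#'   keyed by covariate.
#' @param lags Outcome-lag convention: `"thirds"` (default), `"all"` (every
#'   pre-period month as its own predictor), `"none"`, or a list of month
#'   vectors, each contributing the mean outcome over those months.
#' @return A `predictor_spec` list.
#' @export
predictor_spec <- function(covariates = character(), cov_rule = "mean",
                           lags = "thirds") {
  if (is.character(lags)) {
    lags <- match.arg(lags, c("thirds", "all", "none"))
  } else if (!is.list(lags)) {
    abort("`lags` must be \"thirds\", \"all\", \"none\", or a list of month vectors.")
  }
  if (length(cov_rule) == 1 && length(covariates) > 1) {
    cov_rule <- setNames(rep(cov_rule, length(covariates)), covariates)
  } else if (length(covariates) > 0 && is.null(names(cov_rule))) {
    names(cov_rule) <- covariates
  }
  stopifnot(all(cov_rule %in% c("mean", "last")))
  structure(
    list(covariates = covariates, cov_rule = cov_rule, lags = lags),
    class = "predictor_spec"
  )
}

#' Assemble predictor and pre-period outcome matrices
#'
#' Builds the four matrices the synthetic-control optimization consumes:
#' treated and donor predictor vectors (`X1`, `X0`) and treated and donor
#' pre-period outcome paths (`Z1`, `Z0`). Covariates observed at state-year
#' resolution are repeated across that year's months before pre-period
#' aggregation. Every predictor is z-scored across units (treated + donors)
#' so that the importance weights `V` act on comparable scales; a predictor
#' with zero variance across units cannot be standardized and is dropped
#' with a warning.
#'
#' @param panel A `state_month_panel` holding the outcome rates.
#' @param treated Treated unit identifier.
#' @param donors Character vector of donor identifiers (at least 2).
#' @param pre_period Length-2 month window of the pre-policy period.
#' @param covariates Optional covariate table: data frame with columns
#'   `state`, `year` (or `month`), plus one numeric column per covariate
#'   named in the spec.
#' @param spec A [predictor_spec()].
#' @return An `scm_predictors` list: `X1` (k-vector), `X0` (k x J), `Z1`
#'   (T0-vector), `Z0` (T0 x J), plus predictor names and unit ordering.
#' @export
build_predictors <- function(panel, treated, donors, pre_period,
                             covariates = NULL, spec = predictor_spec()) {
  stopifnot(length(treated) == 1, length(donors) >= 1)
  units <- c(treated, donors)
  Y <- panel_matrix(panel, "rate")
  missing_units <- setdiff(units, rownames(Y))
  if (length(missing_units) > 0) {
    abort(paste0("Units absent from panel: ", paste(missing_units, collapse = ", ")))
  }
  pre_months <- month_seq(pre_period[[1]], pre_period[[2]])
  pre_cols <- format_month(pre_months)
  if (!all(pre_cols %in% colnames(Y))) {
    abort("Pre-period extends outside the panel window.")
  }
  if (length(pre_cols) < 2) {
    abort("Pre-period must contain at least two months.")
  }

  Z <- Y[units, pre_cols, drop = FALSE]

  blocks <- list()

  # Outcome-lag predictors.
  if (identical(spec$lags, "thirds")) {
    idx <- split(seq_along(pre_cols), cut(seq_along(pre_cols), 3, labels = FALSE))
    lag_block <- vapply(idx, function(i) rowMeans(Z[, i, drop = FALSE]), numeric(length(units)))
    colnames(lag_block) <- paste0("outcome_third_", seq_along(idx))
    blocks$lags <- lag_block
  } else if (identical(spec$lags, "all")) {
    lag_block <- Z
    colnames(lag_block) <- paste0("outcome_", pre_cols)
    blocks$lags <- lag_block
  } else if (is.list(spec$lags)) {
    lag_block <- vapply(spec$lags, function(m) {
      cols <- format_month(as_month(m))
      rowMeans(Z[, cols, drop = FALSE])
    }, numeric(length(units)))
    colnames(lag_block) <- paste0("outcome_lag_", seq_along(spec$lags))
    blocks$lags <- lag_block
  }

  # Covariate predictors, expanded to months then aggregated per rule.
  if (length(spec$covariates) > 0) {
    if (is.null(covariates)) {
      abort("Spec names covariates but no covariate table was supplied.")
    }
    cov_monthly <- expand_covariates_monthly(covariates, units, pre_months)
    cov_block <- vapply(spec$covariates, function(nm) {
      if (!nm %in% names(cov_monthly)) {
        abort(paste0("Covariate not found in covariate table: ", nm))
      }
      rule <- spec$cov_rule[[nm]]
      vals <- tidyr::pivot_wider(
        cov_monthly[, c("state", "month", nm)],
        names_from = "month", values_from = dplyr::all_of(nm)
      )
      m <- as.matrix(vals[, -1, drop = FALSE])
      rownames(m) <- vals$state
      if (anyNA(m)) {
        abort(paste0("Covariate ", nm, " is missing for some unit-months in the pre-period."))
      }
      m <- m[units, , drop = FALSE]
      if (rule == "mean") rowMeans(m) else m[, ncol(m)]
    }, numeric(length(units)))
    blocks$covariates <- cov_block
  }

  P <- do.call(cbind, unname(blocks))
  if (is.null(P) || ncol(P) == 0) {
    abort("Predictor spec yields no predictors; include lags or covariates.")
  }

  # Standardize across units; drop unstandardizable constants.
  mu <- colMeans(P)
  sdv <- apply(P, 2, sd)
  zero_var <- sdv == 0
  if (any(zero_var)) {
    warn(paste0(
      "Dropping zero-variance predictor(s): ",
      paste(colnames(P)[zero_var], collapse = ", ")
    ))
    P <- P[, !zero_var, drop = FALSE]
    mu <- mu[!zero_var]
    sdv <- sdv[!zero_var]
  }
  if (ncol(P) == 0) {
    abort("All predictors had zero variance across units.")
  }
  P <- sweep(sweep(P, 2, mu), 2, sdv, "/")

  structure(
    list(
      X1 = P[treated, ],
      X0 = t(P[donors, , drop = FALSE]),
      Z1 = Z[treated, ],
      Z0 = t(Z[donors, , drop = FALSE]),
      predictors = colnames(P),
      treated = treated,
      donors = donors,
      pre_months = pre_months
    ),
    class = "scm_predictors"
  )
}

# Expand a state-year (or already state-month) covariate table to one row per
# unit-month over the requested months.
expand_covariates_monthly <- function(covariates, units, months) {
  covariates <- dplyr::filter(covariates, .data$state %in% units)
  if ("month" %in% names(covariates)) {
    out <- dplyr::mutate(covariates, month = as_month(.data$month))
    return(dplyr::filter(out, .data$month %in% months))
  }
  if (!"year" %in% names(covariates)) {
    abort("Covariate table needs a `year` or `month` column.")
  }
  grid <- tibble::tibble(month = months, year = lubridate::year(months))
  out <- dplyr::inner_join(covariates, grid, by = "year",
                           relationship = "many-to-many")
  dplyr::select(out, -"year")
}
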