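#' In-space placebo ensemble
#'
#' Refits the synthetic control once for the true treated unit and once for
#' each donor falsely designated as treated (against the remaining donors;
#' the true treated unit never enters any placebo's donor pool), all with
#' the same treatment month and predictor spec. The post/pre RMSPE ratio of
#' each fit is the permutation test statistic: placebo units, having no
#' intervention, should show ratios near one.
#'
#' @inheritParams scm_fit
#' @return A `placebo_ensemble`: the treated fit, the placebo fits, and a
#'   `ratios` tibble (`unit`, `is_treated`, `rmspe_pre`, `rmspe_post`,
#'   `ratio`). Failed placebo fits are dropped with a warning and recorded
#'   in `$failures`.
#' @export
run_placebos <- function(panel, treated, donors, treatment_month,
                         covariates = NULL, spec = predictor_spec(),
                         v_method = c("nested", "equal"),
                         n_starts = 10, seed = 1, maxit = 500) {
  v_method <- match.arg(v_method)
  if (length(donors) < 2) {
    abort("Placebo inference needs at least two donors.")
  }
  Y <- panel_matrix(panel, "rate")
  fit_one <- function(unit, pool, unit_seed) {
    scm_fit(
      Y, unit, pool, treatment_month,
      covariates = covariates, spec = spec, v_method = v_method,
      n_starts = n_starts, seed = unit_seed, maxit = maxit
    )
  }
  treated_fit <- fit_one(treated, donors, child_seed(seed, 0))

  failures <- character()
  placebo_fits <- list()
  for (i in seq_along(donors)) {
    d <- donors[[i]]
    fit <- tryCatch(
      fit_one(d, setdiff(donors, d), child_seed(seed, i)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      warn(paste0("Placebo fit failed for ", d, ": ", conditionMessage(fit)))
      failures <- c(failures, d)
    } else {
      placebo_fits[[d]] <- fit
    }
  }

  fits <- c(setNames(list(treated_fit), treated), placebo_fits)
  ratios <- dplyr::bind_rows(purrr::imap(fits, function(f, u) {
    tibble::tibble(
      unit = u, is_treated = u == treated,
      rmspe_pre = f$rmspe_pre, rmspe_post = f$rmspe_post,
      ratio = rmspe_ratio(f)
    )
  }))

  structure(
    list(
      treated = treated,
      treated_fit = treated_fit,
      placebo_fits = placebo_fits,
      ratios = ratios,
      failures = failures,
      n_units = nrow(ratios),
      treatment_month = as_month(treatment_month)
    ),
    class = "placebo_ensemble"
  )
}

#' Ranking p-value from RMSPE ratios
#'
#' Sorts all units (treated plus placebos) by post/pre RMSPE ratio,
#' descending, and reports the treated unit's rank and the permutation
#' p-value `rank / n_units`. The treated rank is one plus the number of
#' units with a strictly larger ratio; ties count against the treated unit
#' (conservative). With the study's geometry of 25 donors the smallest
#' attainable p-value is 1/26.
#'
#' @param ensemble A `placebo_ensemble`.
#' @param filter_ratio Optional pre-fit filter: drop placebos whose
#'   pre-period RMSPE exceeds `filter_ratio` times the treated unit's
#'   (e.g. 5). `NULL` (default) keeps every placebo; the ratio statistic
#'   already self-normalizes for fit quality.
#' @return One-row tibble: `rank`, `n_units`, `p_value`.
#' @export
rank_p_value <- function(ensemble, filter_ratio = NULL) {
  ratios <- ensemble$ratios
  tr <- ratios[ratios$is_treated, ]
  if (nrow(tr) != 1 || is.na(tr$ratio)) {
    abort("Ensemble is missing the treated unit's ratio.")
  }
  if (!is.null(filter_ratio)) {
    keep <- ratios$is_treated |
      ratios$rmspe_pre <= filter_ratio * tr$rmspe_pre
    ratios <- ratios[keep, ]
  }
  n <- nrow(ratios)
  rank <- 1L + sum(ratios$ratio[!ratios$is_treated] > tr$ratio)
  tibble::tibble(rank = rank, n_units = n, p_value = rank / n)
}

#' Pre-period fit gate
#'
#' Declares a treated unit's estimate interpretable only when the pre-policy
#' fit is good in two senses: the pre-period RMSPE is small relative to the
#' unit's own pre-period mean rate (at most `tau1`, default 10%), and it is
#' not an outlier relative to the placebo fits (at most `tau2` times the
#' median placebo pre-period RMSPE, default 2). When the pre-period mean
#' rate is zero only the placebo-relative test applies.
#'
#' @param fit The treated `scm_fit`.
#' @param ensemble The matching `placebo_ensemble`.
#' @param tau1 Maximum pre-period RMSPE as a fraction of the pre-period mean
#'   observed rate.
#' @param tau2 Maximum pre-period RMSPE as a multiple of the median placebo
#'   pre-period RMSPE.
#' @return One-row tibble: `interpretable` plus the measured diagnostics
#'   (`relative_rmspe`, `placebo_multiple`) and a `reasons` list column
#'   naming any failed test (`"tau1"`, `"tau2"`).
#' @export
fit_gate <- function(fit, ensemble = NULL, tau1 = 0.10, tau2 = 2.0) {
  pre_mean <- mean(fit$series$observed[fit$series$period == "pre"])
  relative <- if (pre_mean > 0) fit$rmspe_pre / pre_mean else NA_real_
  placebo_multiple <- NA_real_
  if (!is.null(ensemble) && length(ensemble$placebo_fits) > 0) {
    med <- median(purrr::map_dbl(ensemble$placebo_fits, "rmspe_pre"))
    placebo_multiple <- if (med > 0) fit$rmspe_pre / med else NA_real_
  }
  reasons <- character()
  if (!is.na(relative) && relative > tau1) reasons <- c(reasons, "tau1")
  if (!is.na(placebo_multiple) && placebo_multiple > tau2) reasons <- c(reasons, "tau2")
  tibble::tibble(
    interpretable = length(reasons) == 0,
    relative_rmspe = relative,
    placebo_multiple = placebo_multiple,
    tau1 = tau1,
    tau2 = tau2,
    reasons = list(reasons)
  )
}

#' Yearly effect summaries
#'
#' Aggregates the monthly post-period gaps into implementation-year effects:
#' consecutive 12-month blocks starting at the treatment month. The effect
#' for a year is the sum of its monthly gaps (incidents per 1,000,000
#' residents per year; negative = reduction), and the percent change is the
#' effect relative to the synthetic control's annual rate over the same
#' block. Confidence intervals are either the default "monthly-variation"
#' normal interval, `effect +/- 1.96 * sqrt(12) * sd(monthly gaps)`, or
#' placebo quantiles (the 2.5th and 97.5th percentiles of the placebo
#' units' yearly effects).
#'
#' @param fit The treated `scm_fit`.
#' @param method `"monthly"` (default) or `"placebo"`.
#' @param ensemble Required when `method = "placebo"`.
#' @param conf_level Confidence level for the monthly-variation interval.
#' @return Tibble with one row per implementation year: `year` (1, 2, ...),
#'   `n_months` (12, or fewer for a truncated final year), `effect`,
#'   `ci_low`, `ci_high`, `synthetic_annual`, `percent_change`.
#' @export
yearly_effects <- function(fit, method = c("monthly", "placebo"),
                           ensemble = NULL, conf_level = 0.95) {
  method <- match.arg(method)
  post <- dplyr::filter(fit$series, .data$period == "post")
  if (nrow(post) == 0) {
    abort("Fit has no post-period months.")
  }
  post$year <- (seq_len(nrow(post)) - 1) %/% 12 + 1

  if (method == "placebo") {
    if (is.null(ensemble) || length(ensemble$placebo_fits) == 0) {
      abort("Placebo-quantile intervals need a placebo ensemble.")
    }
    placebo_yearly <- purrr::map(ensemble$placebo_fits, function(f) {
      p <- dplyr::filter(f$series, .data$period == "post")
      p$year <- (seq_len(nrow(p)) - 1) %/% 12 + 1
      dplyr::summarise(dplyr::group_by(p, .data$year),
                       effect = sum(.data$gap), .groups = "drop")
    })
    placebo_yearly <- dplyr::bind_rows(placebo_yearly, .id = "unit")
  }

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- dplyr::summarise(
    dplyr::group_by(post, .data$year),
    n_months = dplyr::n(),
    effect = sum(.data$gap),
    sd_gap = sd(.data$gap),
    synthetic_annual = sum(.data$synthetic),
    .groups = "drop"
  )
  if (method == "monthly") {
    half <- z * sqrt(12) * out$sd_gap
    out$ci_low <- out$effect - half
    out$ci_high <- out$effect + half
  } else {
    qs <- dplyr::summarise(
      dplyr::group_by(placebo_yearly, .data$year),
      q_low = unname(quantile(.data$effect, (1 - conf_level) / 2)),
      q_high = unname(quantile(.data$effect, 1 - (1 - conf_level) / 2)),
      .groups = "drop"
    )
    # The placebo method reports the null band of placebo yearly effects;
    # an effect outside it is extreme relative to the placebo distribution.
    out <- dplyr::left_join(out, qs, by = "year")
    out$ci_low <- out$q_low
    out$ci_high <- out$q_high
    out$q_low <- NULL
    out$q_high <- NULL
  }
  out$percent_change <- ifelse(
    out$synthetic_annual != 0, 100 * out$effect / out$synthetic_annual, NA_real_
  )
  out$sd_gap <- NULL
  dplyr::relocate(out, "year", "n_months", "effect", "ci_low", "ci_high",
                  "synthetic_annual", "percent_change")
}

#' @export
print.placebo_ensemble <- function(x, ...) {
  pv <- rank_p_value(x)
  cat(sprintf(
    "<placebo_ensemble> %s + %d placebos | treated ratio %.3g, rank %d/%d, p = %.4g\n",
    x$treated, length(x$placebo_fits),
    x$ratios$ratio[x$ratios$is_treated], pv$rank, pv$n_units, pv$p_value
  ))
  invisible(x)
}

#' @rdname run_placebos
#' @param x A `placebo_ensemble`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.placebo_ensemble <- function(x, ...) {
  dplyr::arrange(
    dplyr::mutate(x$ratios, rank = rank(-.data$ratio, ties.method = "min")),
    .data$rank
  )
}

#' @rdname run_placebos
#' @exportS3Method generics::glance
glance.placebo_ensemble <- function(x, ...) {
  pv <- rank_p_value(x)
  tibble::tibble(
    treated = x$treated,
    n_units = pv$n_units,
    n_failures = length(x$failures),
    treated_ratio = x$ratios$ratio[x$ratios$is_treated],
    rank = pv$rank,
    p_value = pv$p_value
  )
}

#' Export placebo inference tables
#'
#' Writes the per-unit ratio table and the per-unit gap series (for gap
#' plots) as CSVs.
#'
#' @param ensemble A `placebo_ensemble`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Named vector of files written, invisibly.
#' @export
write_placebo_ensemble <- function(ensemble, dir, prefix = ensemble$treated) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    ratios = file.path(dir, paste0(prefix, "_ratios.csv")),
    gaps = file.path(dir, paste0(prefix, "_placebo_gaps.csv"))
  )
  readr::write_csv(tidy(ensemble), paths[["ratios"]])
  fits <- c(setNames(list(ensemble$treated_fit), ensemble$treated),
            ensemble$placebo_fits)
  gaps <- dplyr::bind_rows(purrr::imap(fits, function(f, u) {
    tibble::tibble(
      month = format_month(f$series$month), unit = u,
      gap = f$series$gap, is_treated = u == ensemble$treated
    )
  }))
  readr::write_csv(gaps, paths[["gaps"]])
  invisible(paths)
}
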