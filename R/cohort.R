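#' Read a policy catalog
#'
#' A policy catalog records, per state, the effective date of its ERPO law
#' (empty when the state has none through the study window) and whether the
#' state has complete covariate coverage.
#'
#' @param path CSV with columns `state`, `effective_date` (ISO-8601 or
#'   empty), `covariate_complete` (0/1 or logical).
#' @return Tibble with columns `state`, `effective_date` (Date, `NA` when
#'   absent), `covariate_complete` (logical).
#' @export
read_policy_catalog <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Policy catalog not found: ", path))
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      state = readr::col_character(),
      effective_date = readr::col_date(),
      covariate_complete = readr::col_logical()
    )
  )
  if (anyDuplicated(raw$state)) {
    abort("Policy catalog lists a state more than once.")
  }
  raw
}

#' The packaged ERPO policy catalog
#'
#' Loads the catalog of the fifty US states shipped with the package: the ten
#' treated-cohort effective dates (California 2016-01-01 through Washington
#' 2016-12-08), the early adopters (Connecticut, Indiana), the 2019-2021
#' adopters, and a covariate-completeness flag that reproduces the study's
#' 25-state donor pool.
#'
#' @return A policy catalog tibble; see [read_policy_catalog()].
#' @export
erpo_policy_catalog <- function() {
  read_policy_catalog(
    system.file("extdata", "policy_catalog.csv", package = "erposcm", mustWork = TRUE)
  )
}

#' Effective-date window filters for the treated cohort
#'
#' A state qualifies for the treated cohort only if its ERPO became effective
#' inside the enrollment window: late enough to leave a usable pre-policy
#' period and early enough to leave a usable post-policy period. Both bounds
#' are inclusive (a law effective exactly on the upper bound still counts).
#' States with no ERPO pass neither filter and remain donor candidates.
#'
#' @param catalog Policy catalog tibble.
#' @param lower,upper Window bounds as dates; defaults 2015-01-01 and
#'   2019-01-01.
#' @return Tibble with columns `state`, `effective_date`, `has_erpo`,
#'   `passes_pre_window` (effective on/after `lower`), `passes_post_window`
#'   (effective on/before `upper`), and `passes_window` (both).
#' @export
apply_window_filters <- function(catalog, lower = as.Date("2015-01-01"),
                                 upper = as.Date("2019-01-01")) {
  lower <- as.Date(lower)
  upper <- as.Date(upper)
  if (lower >= upper) {
    abort("Window lower bound must precede the upper bound.")
  }
  dplyr::transmute(
    catalog,
    state = .data$state,
    effective_date = .data$effective_date,
    has_erpo = !is.na(.data$effective_date),
    passes_pre_window = .data$has_erpo & .data$effective_date >= lower,
    passes_post_window = .data$has_erpo & .data$effective_date <= upper,
    passes_window = .data$passes_pre_window & .data$passes_post_window
  )
}

#' Post-enactment petition-uptake test
#'
#' Tests whether a state actually used its ERPO law after enactment. Because
#' no petitions can be filed before a law exists, pre-enactment volume is
#' structurally zero, and uptake is assessed by a one-sample t-test of the
#' post-enactment monthly petition counts against a mean of zero (one-sided
#' by default: an increase).
#'
#' @param petitions Petition series tibble with columns `state`, `month`,
#'   `petitions` (non-negative monthly counts).
#' @param effective_date The state's ERPO effective date. Months from the
#'   effective month onward count as post-enactment.
#' @param alpha Significance level; default 0.05.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return One-row tibble: `t_statistic`, `p_value`, `n_post`, `pass`,
#'   `status` (`"tested"` or `"inconclusive"` when fewer than two
#'   post-enactment months are available). Degenerate all-equal positive
#'   counts pass with the p-value reported at the machine floor; all-zero
#'   counts fail (no increase occurred).
#' @examples
#' pets <- tibble::tibble(
#'   state = "RI",
#'   month = month_seq("2018-06", "2018-09"),
#'   petitions = c(3L, 5L, 4L, 6L)
#' )
#' petition_increase_test(pets, as.Date("2018-06-01"))
#' @export
petition_increase_test <- function(petitions, effective_date, alpha = 0.05,
                                   alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  post <- petitions$petitions[as_month(petitions$month) >= as_month(effective_date)]
  post <- post[!is.na(post)]
  if (length(post) < 2) {
    return(tibble::tibble(
      t_statistic = NA_real_, p_value = NA_real_, n_post = length(post),
      pass = FALSE, status = "inconclusive"
    ))
  }
  if (sd(post) == 0) {
    if (post[[1]] > 0) {
      # Identical positive counts every month: the increase is certain but the
      # t statistic is undefined; report the p-value at the machine floor.
      return(tibble::tibble(
        t_statistic = Inf, p_value = .Machine$double.xmin,
        n_post = length(post), pass = TRUE, status = "tested"
      ))
    }
    return(tibble::tibble(
      t_statistic = 0, p_value = 1, n_post = length(post),
      pass = FALSE, status = "tested"
    ))
  }
  fit <- t.test(post, mu = 0, alternative = alternative)
  tibble::tibble(
    t_statistic = unname(fit$statistic),
    p_value = fit$p.value,
    n_post = length(post),
    pass = fit$p.value < alpha,
    status = "tested"
  )
}

#' Build the donor pool
#'
#' Donors are the states with no ERPO effective date inside the panel window
#' and no missing years of covariate data. States enacting ERPOs after the
#' treated-cohort enrollment window but inside the panel window (the
#' 2019-2021 adopters) are neither treated nor donors.
#'
#' @param catalog Policy catalog tibble.
#' @param window Length-2 month window; defaults to the study panel window.
#' @return Character vector of donor state identifiers, sorted.
#' @export
build_donor_pool <- function(catalog, window = default_window()) {
  months <- month_seq(window[[1]], window[[2]])
  w_lo <- months[[1]]
  w_hi <- lubridate::ceiling_date(months[[length(months)]], "month") - 1
  in_window <- !is.na(catalog$effective_date) &
    catalog$effective_date >= w_lo & catalog$effective_date <= w_hi
  donors <- catalog$state[!in_window & catalog$covariate_complete]
  if (length(donors) == 0) {
    abort("Donor pool is empty under this catalog and window.")
  }
  sort(donors)
}

#' Select the treated cohort and donor pool
#'
#' Applies the three treated-state inclusion filters — enacted late enough
#' for a pre-period, early enough for a post-period, and showing a
#' significant post-enactment increase in petitions — and partitions states
#' into treated, donor, and excluded sets.
#'
#' @param catalog Policy catalog tibble.
#' @param petitions Petition series tibble (`state`, `month`, `petitions`)
#'   covering the candidate treated states.
#' @param window Panel month window for donor eligibility.
#' @param lower,upper Treated-cohort effective-date window bounds.
#' @param alpha Petition-test significance level.
#' @param alternative Petition-test alternative; see
#'   [petition_increase_test()].
#' @return A `cohort_decision` tibble, one row per state: `state`, `role`
#'   (`"treated"`, `"donor"`, `"excluded"`), `included`, `failed_filters`
#'   (list column naming the failed filters), `effective_date`,
#'   `t_statistic`, `p_value`.
#' @export
select_cohort <- function(catalog, petitions, window = default_window(),
                          lower = as.Date("2015-01-01"),
                          upper = as.Date("2019-01-01"),
                          alpha = 0.05,
                          alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  wf <- apply_window_filters(catalog, lower = lower, upper = upper)
  donors <- build_donor_pool(catalog, window = window)

  decisions <- purrr::map(seq_len(nrow(wf)), function(i) {
    row <- wf[i, ]
    failed <- character()
    t_stat <- NA_real_
    p_val <- NA_real_
    if (!row$has_erpo) {
      failed <- "no_erpo"
    } else {
      if (!row$passes_pre_window) failed <- c(failed, "pre_window")
      if (!row$passes_post_window) failed <- c(failed, "post_window")
      if (row$passes_window) {
        pets <- dplyr::filter(petitions, .data$state == row$state)
        if (nrow(pets) == 0) {
          failed <- c(failed, "petition_test")
        } else {
          pt <- petition_increase_test(
            pets, row$effective_date,
            alpha = alpha, alternative = alternative
          )
          t_stat <- pt$t_statistic
          p_val <- pt$p_value
          if (!pt$pass) failed <- c(failed, "petition_test")
        }
      }
    }
    tibble::tibble(
      state = row$state,
      included = length(failed) == 0,
      failed_filters = list(failed),
      effective_date = row$effective_date,
      t_statistic = t_stat,
      p_value = p_val
    )
  })
  decisions <- dplyr::bind_rows(decisions)
  decisions$role <- dplyr::case_when(
    decisions$included ~ "treated",
    decisions$state %in% donors ~ "donor",
    TRUE ~ "excluded"
  )
  out <- dplyr::relocate(decisions, "state", "role", "included")
  class(out) <- c("cohort_decision", class(out))
  out
}

#' @export
print.cohort_decision <- function(x, ...) {
  cat(sprintf(
    "<cohort_decision> %d treated, %d donors, %d excluded\n",
    sum(x$role == "treated"), sum(x$role == "donor"), sum(x$role == "excluded")
  ))
  NextMethod()
}
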