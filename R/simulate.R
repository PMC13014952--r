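#' Configure the factor-model panel simulator
#'
#' The simulator emulates the structure of the study's state-month panel: a
#' shared seasonal baseline, a small number of latent factors with
#' unit-specific loadings (the source of cross-state heterogeneity that the
#' synthetic control must match), a common pandemic-era level shock, and
#' Poisson count noise whose relative size shrinks with state population --
#' small states produce volatile monthly rates, as in the real data.
#'
#' The latent monthly rate for unit `i` in month `t` is
#' `lambda_it = max(0, delta_t + sum_r F_rt * mu_ir + covid_t + effect_it + eps_it)`
#' in incidents per 1,000,000 residents, with counts drawn as
#' `Poisson(lambda_it * pop_i / 1e6)`.
#'
#' @param n_treated,n_donors Number of treated and donor units (defaults 10
#'   and 25, the study's geometry).
#' @param window Month window, default 2014-01 through 2021-12 (96 months).
#' @param n_factors Number of latent factors (default 2).
#' @param baseline_annual_rate Expected incidents per 1,000,000 residents per
#'   year under no effect (default 60, matching the scale at which a
#'   mid-single-digit monthly rate and ~60/year baseline arise).
#' @param factor_share Share of the baseline carried by the latent factors
#'   (default 0.5); the remainder is the common seasonal trend.
#' @param factor_sd Relative volatility of each factor path (default 0.3).
#' @param season_amp Seasonal amplitude of the common trend (default 0.1).
#' @param noise_sd Additive Gaussian rate noise, per 1M per month
#'   (default 0.3); must be positive (set arbitrarily small to approximate
#'   the noiseless model).
#' @param covid_start,covid_magnitude Pandemic shock: from `covid_start`
#'   (default 2020-03) the latent rate rises by `covid_magnitude` (default
#'   0.20) times the monthly baseline, for every state.
#' @param pop_range Range of state populations, drawn log-uniformly per
#'   state (default 6e5 to 8e6).
#' @param overlap If `TRUE` (default) treated loadings are drawn inside the
#'   donor convex hull, so a good synthetic control exists; if `FALSE` they
#'   are placed outside it, to exercise the pre-period fit gate.
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A `factor_config` list.
#' @export
factor_config <- function(n_treated = 10, n_donors = 25,
                          window = default_window(), n_factors = 2,
                          baseline_annual_rate = 60, factor_share = 0.5,
                          factor_sd = 0.3, season_amp = 0.1, noise_sd = 0.3,
                          covid_start = "2020-03", covid_magnitude = 0.20,
                          pop_range = c(6e5, 8e6), overlap = TRUE, seed = 1) {
  stopifnot(n_donors >= 2, noise_sd > 0, baseline_annual_rate > 0)
  structure(
    list(
      n_treated = n_treated, n_donors = n_donors, window = window,
      n_factors = n_factors, baseline_annual_rate = baseline_annual_rate,
      factor_share = factor_share, factor_sd = factor_sd,
      season_amp = season_amp, noise_sd = noise_sd,
      covid_start = covid_start, covid_magnitude = covid_magnitude,
      pop_range = pop_range, overlap = overlap, seed = seed
    ),
    class = "factor_config"
  )
}

#' Specify an injected treatment-effect profile
#'
#' @param shape `"none"` (no effect), `"step"` (a constant shift of `delta`
#'   per month from `start` onward), or `"ramp"` (a shift growing linearly
#'   with time since `start`, reaching `delta` per month at month 12 and
#'   continuing to grow -- the pattern of effects strengthening over
#'   implementation years).
#' @param delta Signed monthly effect in incidents per 1,000,000 residents
#'   (negative = reduction).
#' @param start First affected month; defaults to the unit's effective date.
#' @return An `effect_profile` list.
#' @export
effect_profile <- function(shape = c("none", "step", "ramp"), delta = 0,
                           start = NULL) {
  shape <- match.arg(shape)
  if (shape == "none") delta <- 0
  structure(list(shape = shape, delta = delta, start = start),
            class = "effect_profile")
}

effect_series <- function(profile, months, effective_date) {
  start <- as_month(profile$start %||% effective_date)
  since <- as.numeric((lubridate::year(months) - lubridate::year(start)) * 12 +
                        lubridate::month(months) - lubridate::month(start))
  out <- numeric(length(months))
  on <- since >= 0
  if (profile$shape == "step") {
    out[on] <- profile$delta
  } else if (profile$shape == "ramp") {
    out[on] <- profile$delta * (since[on] + 1) / 12
  }
  out
}

#' Generate a ground-truth-annotated study panel
#'
#' Draws a complete simulated study: latent rates from the factor model,
#' Poisson incident counts, populations, effective dates for the treated
#' units (spread over 2016-2019 as in the study cohort), covariates that are
#' noisy linear functions of the factor loadings (hence genuinely
#' informative predictors), and the injected true effect series.
#'
#' @param config A [factor_config()].
#' @param effects An [effect_profile()] applied to every treated unit, or a
#'   named list of profiles keyed by treated unit id. Default: no effect.
#' @param observation `"poisson"` (default: counts are Poisson draws) or
#'   `"exact"` (rates equal the latent rates; for noiseless recovery
#'   checks).
#' @return A `simulated_study` list: `panel` (a `state_month_panel` of
#'   all-violence rates), `population` (state-year table), `covariates`
#'   (state-year table), `effective_dates` (named Date vector for treated
#'   units), `treated`, `donors`, `truth` (latent rate matrix, loadings, and
#'   the injected effect series per treated unit), and `config`.
#' @export
generate_panel <- function(config, effects = effect_profile("none"),
                           observation = c("poisson", "exact")) {
  observation <- match.arg(observation)
  stopifnot(inherits(config, "factor_config"))
  months <- month_seq(config$window[[1]], config$window[[2]])
  Tm <- length(months)
  treated <- sprintf("T%02d", seq_len(config$n_treated))
  donors <- sprintf("D%02d", seq_len(config$n_donors))
  units <- c(treated, donors)
  n <- length(units)
  b <- config$baseline_annual_rate / 12

  if (inherits(effects, "effect_profile")) {
    effects <- setNames(rep(list(effects), length(treated)), treated)
  }

  sim <- local_seed(config$seed, {
    # Latent factor paths: positive, mean ~1, AR(1)-smoothed.
    Fp <- vapply(seq_len(config$n_factors), function(r) {
      z <- as.numeric(stats::arima.sim(list(ar = 0.8), n = Tm, sd = sqrt(1 - 0.8^2)))
      pmax(0, 1 + config$factor_sd * z)
    }, numeric(Tm))

    # Loadings: donors uniform; treated inside (or outside) the donor hull.
    mu_d <- matrix(runif(config$n_donors * config$n_factors, 0.4, 1.6),
                   config$n_donors, config$n_factors)
    mu_t <- if (config$overlap) {
      t(vapply(seq_len(config$n_treated), function(i) {
        a <- runif(config$n_donors)
        a <- a^4  # concentrate on a few donors
        drop((a / sum(a)) %*% mu_d)
      }, numeric(config$n_factors)))
    } else {
      # Push loadings beyond the donor range so no convex combination matches.
      t(vapply(seq_len(config$n_treated), function(i) {
        apply(mu_d, 2, max) + runif(config$n_factors, 0.8, 1.4)
      }, numeric(config$n_factors)))
    }
    mu <- rbind(mu_t, mu_d)
    rownames(mu) <- units

    pop <- round(exp(runif(n, log(config$pop_range[[1]]), log(config$pop_range[[2]]))))
    names(pop) <- units

    dates_grid <- month_seq("2016-01", "2019-01")
    eff_idx <- round(seq(1, length(dates_grid), length.out = max(config$n_treated, 1)))
    effective_dates <- setNames(dates_grid[eff_idx], treated)

    season <- 1 + config$season_amp * sin(2 * pi * lubridate::month(months) / 12)
    delta_t <- b * (1 - config$factor_share) * season
    covid <- ifelse(months >= as_month(config$covid_start),
                    config$covid_magnitude * b, 0)

    factor_level <- b * config$factor_share / config$n_factors
    lam_core <- matrix(rep(delta_t + covid, n), n, Tm, byrow = TRUE) +
      mu %*% t(Fp * factor_level)

    eff_mat <- matrix(0, n, Tm, dimnames = list(units, format_month(months)))
    for (u in treated) {
      eff_mat[u, ] <- effect_series(effects[[u]], months, effective_dates[[u]])
    }

    eps <- matrix(rnorm(n * Tm, 0, config$noise_sd), n, Tm)
    lambda <- lam_core + eff_mat + eps
    lambda[lambda < 0] <- 0
    dimnames(lambda) <- list(units, format_month(months))

    expected <- lambda * pop / 1e6
    counts <- if (observation == "poisson") {
      matrix(rpois(n * Tm, expected), n, Tm, dimnames = dimnames(lambda))
    } else {
      expected
    }
    list(
      lambda = lambda, counts = counts, pop = pop, mu = mu,
      effective_dates = effective_dates, eff_mat = eff_mat, Fp = Fp
    )
  })

  years <- sort(unique(lubridate::year(months)))
  population <- tidyr::expand_grid(state = units, year = years)
  population$population <- sim$pop[population$state]

  panel_long <- tibble::as_tibble(expand.grid(
    month = months, state = units, stringsAsFactors = FALSE
  ))[, c("state", "month")]
  panel_long <- dplyr::arrange(panel_long, .data$state, .data$month)
  idx <- cbind(
    match(panel_long$state, units),
    match(format_month(panel_long$month), format_month(months))
  )
  panel_long$count <- sim$counts[idx]
  panel_long$population <- sim$pop[panel_long$state]
  panel_long$rate <- panel_long$count * 1e6 / panel_long$population
  panel <- new_state_month_panel(panel_long, category = "all_violence",
                                 window = config$window)

  covariates <- generate_covariates(sim$mu, years, seed = child_seed(config$seed, 17))

  true_effects <- tibble::as_tibble(expand.grid(
    month = months, state = treated, stringsAsFactors = FALSE
  ))[, c("state", "month")]
  true_effects$effect <- sim$eff_mat[cbind(
    match(true_effects$state, units),
    match(format_month(true_effects$month), format_month(months))
  )]

  structure(
    list(
      panel = panel,
      population = population,
      covariates = covariates,
      effective_dates = sim$effective_dates,
      treated = treated,
      donors = donors,
      truth = list(
        lambda = sim$lambda, loadings = sim$mu, factors = sim$Fp,
        effects = true_effects, counts = sim$counts
      ),
      config = config
    ),
    class = "simulated_study"
  )
}

# Covariates as noisy linear functions of the latent loadings, so they carry
# real information about the factor structure the fit must match.
generate_covariates <- function(mu, years, seed, n_covariates = 4,
                                beta_scale = 1, noise = 0.15) {
  local_seed(seed, {
    n <- nrow(mu)
    k <- ncol(mu)
    out <- purrr::map(seq_len(n_covariates), function(c_i) {
      beta <- rnorm(k, 0, beta_scale)
      base <- drop(mu %*% beta) + rnorm(n, 0, noise)
      tibble::tibble(
        state = rep(rownames(mu), each = length(years)),
        year = rep(years, n),
        value = rep(base, each = length(years)) +
          rnorm(n * length(years), 0, noise / 3),
        name = paste0("cov_", c_i)
      )
    })
    tidyr::pivot_wider(dplyr::bind_rows(out), names_from = "name",
                       values_from = "value")
  })
}

#' Disaggregate a simulated panel into incident records
#'
#' Splits every state-month count into incident records with multinomial
#' intent draws and Bernoulli fatalities, producing a table in exactly the
#' dialect [read_incidents()] consumes. Aggregating the records back with
#' [aggregate_rates()] for `all_violence` reproduces the panel counts
#' cell-for-cell.
#'
#' @param study A `simulated_study` from [generate_panel()].
#' @param intent_mix Proportions over assault / self-harm / unintentional
#'   intents (must sum to 1). Mixed-intent multi-victim incidents are not
#'   emitted.
#' @param fatality Probability an incident of each intent is fatal.
#' @param seed Integer seed.
#' @return Tibble of incident records (`state`, `date`, `n_injured`,
#'   `n_killed`, `intent`, `mass_shooting`).
#' @export
generate_incidents <- function(study,
                               intent_mix = c(assault = 0.7, self_harm = 0.2,
                                              unintentional = 0.1),
                               fatality = c(assault = 0.25, self_harm = 0.85,
                                            unintentional = 0.05),
                               seed = child_seed(study$config$seed, 29)) {
  stopifnot(abs(sum(intent_mix) - 1) < 1e-8,
            all(names(intent_mix) %in% incident_intents()),
            all(names(intent_mix) %in% names(fatality)))
  cells <- dplyr::filter(study$panel, .data$count > 0)
  if (nrow(cells) == 0) {
    abort("Simulated panel has no incidents to disaggregate.")
  }
  local_seed(seed, {
    recs <- purrr::map(seq_len(nrow(cells)), function(i) {
      n_inc <- as.integer(cells$count[[i]])
      intents <- rep(names(intent_mix), rmultinom(1, n_inc, intent_mix)[, 1])
      fatal <- rbinom(n_inc, 1, fatality[intents]) == 1
      n_killed <- ifelse(fatal, 1L, 0L)
      n_injured <- ifelse(fatal, 0L, 1L + rpois(n_inc, 0.2))
      days <- sample(lubridate::days_in_month(cells$month[[i]]), n_inc, replace = TRUE)
      tibble::tibble(
        state = cells$state[[i]],
        date = cells$month[[i]] + days - 1,
        n_injured = as.integer(n_injured),
        n_killed = n_killed,
        intent = intents,
        mass_shooting = n_injured + n_killed >= 4
      )
    })
    dplyr::bind_rows(recs)
  })
}

#' Generate petition series
#'
#' Petition counts are structurally zero before a state's ERPO effective
#' date and Poisson with a configurable mean (optionally growing year on
#' year) afterwards. States without an effective date get an all-zero
#' series.
#'
#' @param states Character vector of states.
#' @param effective_dates Named Date vector (may omit states or hold `NA`
#'   for never-treated states).
#' @param window Month window for the series.
#' @param mean_rate Mean monthly post-enactment petition count (default 5).
#' @param growth Year-on-year multiplicative growth in the post-enactment
#'   mean (default 0).
#' @param seed Integer seed.
#' @return Tibble: `state`, `month`, `petitions`.
#' @export
generate_petitions <- function(states, effective_dates,
                               window = default_window(), mean_rate = 5,
                               growth = 0, seed = 1) {
  stopifnot(mean_rate >= 0)
  months <- month_seq(window[[1]], window[[2]])
  local_seed(seed, {
    out <- purrr::map(states, function(s) {
      eff <- effective_dates[s]
      eff <- if (is.null(eff) || length(eff) == 0) NA else unname(eff)
      pets <- integer(length(months))
      if (!is.na(eff)) {
        post <- months >= as_month(eff)
        yrs <- pmax(0, lubridate::year(months) - lubridate::year(as_month(eff)))
        mean_m <- mean_rate * (1 + growth)^yrs
        pets[post] <- rpois(sum(post), mean_m[post])
      }
      tibble::tibble(state = s, month = months, petitions = pets)
    })
    dplyr::bind_rows(out)
  })
}

#' Materialize a simulated study as CSV files plus a manifest
#'
#' Writes the incident, population, covariate, policy-catalog, and petition
#' CSVs in the dialects the ingestion functions consume, together with a
#' JSON manifest recording the configuration, seed, and ground-truth effect
#' series. Byte-identical across runs for the same study object.
#'
#' @param study A `simulated_study`.
#' @param dir Output directory.
#' @param petitions Optional precomputed petition tibble; generated from the
#'   study's effective dates by default.
#' @return Named vector of the files written, invisibly.
#' @export
write_simulated_study <- function(study, dir,
                                  petitions = generate_petitions(
                                    c(study$treated, study$donors),
                                    study$effective_dates,
                                    window = study$config$window,
                                    seed = child_seed(study$config$seed, 31)
                                  )) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  incidents <- generate_incidents(study)
  paths <- c(
    incidents = file.path(dir, "incidents.csv"),
    population = file.path(dir, "population.csv"),
    covariates = file.path(dir, "covariates.csv"),
    policy_catalog = file.path(dir, "policy_catalog.csv"),
    petitions = file.path(dir, "petitions.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  readr::write_csv(incidents, paths[["incidents"]])
  readr::write_csv(study$population, paths[["population"]])
  readr::write_csv(study$covariates, paths[["covariates"]])
  catalog <- tibble::tibble(
    state = c(study$treated, study$donors),
    effective_date = c(unname(study$effective_dates),
                       rep(as.Date(NA), length(study$donors))),
    covariate_complete = TRUE
  )
  readr::write_csv(catalog, paths[["policy_catalog"]])
  readr::write_csv(
    dplyr::mutate(petitions, month = format_month(.data$month)),
    paths[["petitions"]]
  )
  manifest <- list(
    config = study$config[setdiff(names(study$config), "window")],
    window = as.character(study$config$window),
    seed = study$config$seed,
    treated = study$treated,
    donors = study$donors,
    effective_dates = setNames(
      as.character(study$effective_dates), names(study$effective_dates)
    ),
    true_effects = dplyr::mutate(
      study$truth$effects, month = format_month(.data$month)
    )
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
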