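test_that("the generator is deterministic given the seed", {
  cfg <- factor_config(n_treated = 2, n_donors = 4,
                       window = c("2015-01", "2017-12"), seed = 42)
  s1 <- generate_panel(cfg)
  s2 <- generate_panel(cfg)
  expect_identical(s1$panel, s2$panel)
  expect_identical(s1$truth$lambda, s2$truth$lambda)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulated_study(s1, d1)
  write_simulated_study(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("counts are Poisson draws around the recorded latent rates", {
  study <- generate_panel(factor_config(
    n_treated = 2, n_donors = 10, seed = 12, pop_range = c(1e6, 5e6)
  ))
  expected <- study$truth$lambda * study$population$population[
    match(rownames(study$truth$lambda), study$population$state)
  ] / 1e6
  z <- (study$truth$counts - expected) / sqrt(pmax(expected, 1e-9))
  # standardized Poisson residuals: mean near zero over all cells
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)) + 0.05)
  expect_lt(abs(sd(as.numeric(z)) - 1), 0.1)
  # panel rates reproduce counts / population
  expect_equal(study$panel$rate,
               study$panel$count * 1e6 / study$panel$population)
})

test_that("a noiseless mid-donor treated unit is recovered almost exactly", {
  # two donors: the convex weights matching the treated loadings are unique
  cfg <- factor_config(n_treated = 1, n_donors = 2, noise_sd = 1e-9,
                       factor_sd = 0.4, seed = 5)
  study <- generate_panel(cfg, observation = "exact")
  lam <- study$truth$lambda
  lam["T01", ] <- (lam["D01", ] + lam["D02", ]) / 2
  panel <- study$panel
  for (u in rownames(lam)) {
    panel$rate[panel$state == u] <- lam[u, ]
  }
  panel <- as_state_month_panel(panel)
  fit <- scm_fit(panel, "T01", study$donors, "2018-01",
                 spec = predictor_spec(lags = "all"), v_method = "equal")
  expect_equal(fit$weights$weight, c(0.5, 0.5), tolerance = 1e-6)
  expect_lt(max(abs(fit$series$gap)), 1e-7)

  # with more donors the weights are not identified (the factor structure
  # makes many convex combinations equivalent) but the fit still is
  cfg6 <- factor_config(n_treated = 1, n_donors = 6, noise_sd = 1e-9,
                        factor_sd = 0.4, seed = 5)
  study6 <- generate_panel(cfg6, observation = "exact")
  lam6 <- study6$truth$lambda
  lam6["T01", ] <- (lam6["D01", ] + lam6["D02", ]) / 2
  panel6 <- study6$panel
  for (u in rownames(lam6)) {
    panel6$rate[panel6$state == u] <- lam6[u, ]
  }
  panel6 <- as_state_month_panel(panel6)
  fit6 <- scm_fit(panel6, "T01", study6$donors, "2018-01",
                  spec = predictor_spec(lags = "all"), v_method = "equal")
  expect_lt(max(abs(fit6$series$gap)), 1e-6)
})

test_that("injected step effects are recorded in the ground truth", {
  delta <- -0.10 * 5  # 10% of a 5 per-1M monthly baseline
  cfg <- factor_config(n_treated = 1, n_donors = 4, seed = 9,
                       baseline_annual_rate = 60)
  study <- generate_panel(cfg, effects = effect_profile("step", delta = delta))
  eff <- study$truth$effects
  tm <- as_month(study$effective_dates[["T01"]])
  post <- eff$effect[eff$month >= tm]
  expect_true(all(post == delta))
  expect_true(all(eff$effect[eff$month < tm] == 0))
  # first implementation year totals 12 * delta
  expect_equal(sum(post[1:12]), 12 * delta)
})

test_that("ramp effects grow monotonically", {
  study <- generate_panel(
    factor_config(n_treated = 1, n_donors = 4, seed = 10),
    effects = effect_profile("ramp", delta = -1)
  )
  eff <- study$truth$effects
  post <- eff$effect[eff$effect != 0]
  expect_true(all(diff(abs(post)) > 0))
})

test_that("incident disaggregation reproduces the panel and honors the mixture", {
  study <- tiny_study(seed = 14, n_donors = 4)
  recs <- generate_incidents(study, seed = 3)
  back <- aggregate_rates(filter_injurious(recs), study$population,
                          category = "all_violence",
                          window = study$config$window,
                          states = sort(c(study$treated, study$donors)))
  expect_equal(panel_matrix(back, "count"),
               panel_matrix(study$panel, "count"))

  pure <- generate_incidents(study, intent_mix = c(assault = 1, self_harm = 0,
                                                   unintentional = 0),
                             fatality = c(assault = 0, self_harm = 0,
                                          unintentional = 0),
                             seed = 4)
  sets <- classify_incident(pure)
  expect_true(all(vapply(sets, function(s) "nonfatal_assault" %in% s, logical(1))))

  fatal_sh <- generate_incidents(study,
                                 intent_mix = c(assault = 0.5, self_harm = 0.5,
                                                unintentional = 0),
                                 fatality = c(assault = 0.2, self_harm = 1,
                                              unintentional = 0),
                                 seed = 6)
  sh <- fatal_sh[fatal_sh$intent == "self_harm", ]
  expect_true(all(sh$n_killed == 1))
  suicide_count <- sum(vapply(classify_incident(fatal_sh),
                              function(s) "suicide" %in% s, logical(1)))
  expect_equal(suicide_count, nrow(sh))
})

test_that("petition series are zero before enactment and active after", {
  dates <- c(A = as.Date("2018-06-01"), B = as.Date(NA))
  pets <- generate_petitions(c("A", "B"), dates, mean_rate = 5, seed = 2,
                             window = c("2016-01", "2021-12"))
  a <- pets[pets$state == "A", ]
  expect_true(all(a$petitions[a$month < as.Date("2018-06-01")] == 0))
  expect_gt(sum(a$petitions[a$month >= as.Date("2018-06-01")]), 0)
  expect_true(all(pets$petitions[pets$state == "B"] == 0))

  silent <- generate_petitions("C", c(C = as.Date("2018-06-01")),
                               mean_rate = 0, seed = 3)
  expect_true(all(silent$petitions == 0))
  expect_false(petition_increase_test(silent, as.Date("2018-06-01"))$pass)
})

test_that("a healthy petition series passes the uptake test across seeds", {
  passes <- vapply(1:50, function(s) {
    pets <- generate_petitions("A", c(A = as.Date("2018-01-01")),
                               window = c("2016-01", "2020-12"),
                               mean_rate = 5, seed = s)
    petition_increase_test(pets, as.Date("2018-01-01"))$pass
  }, logical(1))
  expect_gte(mean(passes), 0.98)
})

test_that("year-on-year growth raises later petition volumes", {
  pets <- generate_petitions("A", c(A = as.Date("2016-01-01")),
                             window = c("2016-01", "2021-12"),
                             mean_rate = 10, growth = 0.5, seed = 8)
  yearly <- dplyr::summarise(
    dplyr::group_by(pets, year = lubridate::year(month)),
    total = sum(petitions), .groups = "drop"
  )
  expect_gt(yearly$total[6], yearly$total[1])
})

test_that("overlap control drives the fit gate", {
  gate_status <- function(overlap, seed) {
    study <- generate_panel(factor_config(
      n_treated = 1, n_donors = 8, overlap = overlap, seed = seed,
      noise_sd = 0.05, pop_range = c(4e6, 8e6),
      window = c("2015-01", "2019-12")
    ), observation = "exact")
    ens <- run_placebos(study$panel, "T01", study$donors,
                        study$effective_dates[["T01"]], v_method = "equal")
    fit_gate(ens$treated_fit, ens)$interpretable
  }
  out_hull <- vapply(1:5, function(s) gate_status(FALSE, s), logical(1))
  expect_true(all(!out_hull))
  in_hull <- vapply(1:5, function(s) gate_status(TRUE, s), logical(1))
  expect_gte(mean(in_hull), 0.6)
})
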